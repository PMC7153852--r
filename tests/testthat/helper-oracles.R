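# Independent brute-force oracles used across the suite.  These deliberately
# share no code with the implementation paths they check.

# normalized cross-correlation by direct looping over all valid offsets
oracle_zncc <- function(frame, template) {
  H <- nrow(frame); W <- ncol(frame)
  h <- nrow(template); w <- ncol(template)
  out <- matrix(NA_real_, H - h + 1, W - w + 1)
  tv <- as.vector(template)
  for (i in seq_len(H - h + 1))
    for (j in seq_len(W - w + 1)) {
      win <- as.vector(frame[i:(i + h - 1), j:(j + w - 1)])
      out[i, j] <- if (sd(win) == 0) 0 else cor(win, tv)
    }
  out
}

# per-pixel distances to the two nearest cells by exhaustive scanning
oracle_border_weights <- function(mask, w0 = 10, sigma = 5) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- mmtrack::label_components(mask)
  ncell <- max(lab)
  f <- mean(mask)
  wc <- if (f %in% c(0, 1)) matrix(1, H, W) else {
    m <- matrix(0.5 / (1 - f), H, W); m[mask == 1] <- 0.5 / f; m
  }
  if (ncell < 2) return(wc)
  comp_px <- lapply(seq_len(ncell), function(k)
    which(lab == k, arr.ind = TRUE))
  out <- wc
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] == 1) next
    d <- vapply(comp_px, function(px)
      sqrt(min((px[, 1] - i)^2 + (px[, 2] - j)^2)), numeric(1))
    d <- sort(d)
    out[i, j] <- wc[i, j] + w0 * exp(-(d[1] + d[2])^2 / (2 * sigma^2))
  }
  out
}

# scalar-loop loss oracles
oracle_wbce <- function(target, prediction, weights) {
  eps <- 1e-7
  total <- 0
  for (i in seq_len(nrow(target))) for (j in seq_len(ncol(target))) {
    p <- min(max(prediction[i, j], eps), 1 - eps)
    total <- total + weights[i, j] *
      (-target[i, j] * log(p) - (1 - target[i, j]) * log(1 - p))
  }
  total / length(target)
}

oracle_cce <- function(targets, predictions) {
  eps <- 1e-7
  total <- 0
  for (i in seq_len(dim(targets)[1])) for (j in seq_len(dim(targets)[2])) {
    k <- which(targets[i, j, ] == 1)
    total <- total - log(min(max(predictions[i, j, k], eps), 1))
  }
  total / (dim(targets)[1] * dim(targets)[2])
}

# exhaustive enumeration of all valid assignment sets of a score matrix,
# with the conflict rule (exactly tied top scores -> forced new-cell root),
# returning the maximum total overlap and every optimal link set
oracle_resolve <- function(mother, daughter, areas, min_overlap = 0.5) {
  ns <- nrow(mother); nc <- ncol(mother)
  links_for_cell <- function(j) {
    out <- list()
    for (i in seq_len(ns)) {
      if (mother[i, j] + daughter[i, j] < min_overlap * areas[j]) next
      if (mother[i, j] > 0)
        out[[length(out) + 1]] <- list(i = i, type = "mother",
                                       s = mother[i, j])
      if (daughter[i, j] > 0)
        out[[length(out) + 1]] <- list(i = i, type = "daughter",
                                       s = daughter[i, j])
    }
    out
  }
  cand <- lapply(seq_len(nc), links_for_cell)
  forced_root <- vapply(seq_len(nc), function(j) {
    if (length(cand[[j]]) == 0) return(TRUE)
    tops <- tapply(vapply(cand[[j]], `[[`, numeric(1), "s"),
                   vapply(cand[[j]], `[[`, numeric(1), "i"), max)
    sum(tops == max(tops)) >= 2
  }, logical(1))
  best_total <- -1; best_sets <- list()
  recurse <- function(j, used_m, used_d, acc, total) {
    if (j > nc) {
      if (total > best_total) {
        best_total <<- total; best_sets <<- list(acc)
      } else if (total == best_total) {
        best_sets[[length(best_sets) + 1]] <<- acc
      }
      return()
    }
    recurse(j + 1, used_m, used_d, acc, total)   # cell j stays a root
    if (!forced_root[j]) for (op in cand[[j]]) {
      if (op$type == "mother" && !used_m[op$i]) {
        um <- used_m; um[op$i] <- TRUE
        recurse(j + 1, um, used_d,
                c(acc, list(c(op$i, j, 1, op$s))), total + op$s)
      }
      if (op$type == "daughter" && !used_d[op$i]) {
        ud <- used_d; ud[op$i] <- TRUE
        recurse(j + 1, used_m, ud,
                c(acc, list(c(op$i, j, 2, op$s))), total + op$s)
      }
    }
  }
  recurse(1, logical(ns), logical(ns), list(), 0)
  list(total = best_total, sets = best_sets)
}

# small ground truth with rendered frames for integration-style tests
tiny_movie <- function(seed = 42, n_frames = 25, growth = log(2) / 40) {
  mmtrack::simulate_movie(
    mmtrack::sim_params(chamber_height = 128, chamber_width = 32,
                        cell_width = 11, initial_length = 20,
                        division_length = 40, growth_rate = growth,
                        n_frames = n_frames),
    seed = seed)
}

# perfect tracking outputs straight from ground truth (network bypass)
gt_bypass_assignments <- function(gt) {
  lin <- gt$lineage
  H <- gt$dim[1]; W <- gt$dim[2]
  n <- gt$n_frames
  assigns <- vector("list", n - 1)
  for (t in seq_len(n - 1)) {
    labs <- sort(unique(gt$masks[[t]][gt$masks[[t]] > 0]))
    outs <- lapply(labs, function(l) {
      tr <- lin$tracks[[as.character(l)]]
      mo <- matrix(FALSE, H, W); da <- matrix(FALSE, H, W)
      if (!is.null(tr$regions[[t + 1]])) mo[tr$regions[[t + 1]]] <- TRUE
      dd <- tr$daughter_ids[vapply(tr$daughter_ids, function(d)
        lin$tracks[[as.character(d)]]$first_frame == t + 1, logical(1))]
      if (length(dd) == 1)
        da[lin$tracks[[as.character(dd)]]$regions[[t + 1]]] <- TRUE
      list(mother = mo, daughter = da)
    })
    names(outs) <- labs
    sc <- mmtrack::attribute_scores(outs, gt$masks[[t + 1]])
    assigns[[t]] <- mmtrack::resolve_assignments(sc)
  }
  assigns
}
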
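#' Build the per-frame score matrix from tracking outputs
#'
#' Counts, for every seed cell of frame `t` and every segmented cell of
#' frame `t+1`, how many pixels of the seed's mother / daughter tracking
#' output fall on that cell.
#'
#' @param track_outputs named list, one entry per seed, each a list with
#'   logical matrices `mother` and `daughter` (as returned by
#'   [track_cell()]).
#' @param labeled_seg labelled segmentation of the current frame.
#' @return an `mm_scores` object: integer matrices `mother` and `daughter`
#'   (rows = seeds, cols = cells), `cell_areas`, `seed_ids`, `cell_ids`.
#' @export
attribute_scores <- function(track_outputs, labeled_seg) {
  cell_ids <- sort(unique(labeled_seg[labeled_seg > 0]))
  n_seed <- length(track_outputs); n_cell <- length(cell_ids)
  seed_ids <- names(track_outputs)
  if (is.null(seed_ids)) seed_ids <- as.character(seq_len(n_seed))
  count_on <- function(maskmat) {
    lab <- labeled_seg[maskmat]
    lab <- lab[lab > 0]
    as.integer(table(factor(lab, levels = cell_ids)))
  }
  mo <- matrix(0L, n_seed, n_cell, dimnames = list(seed_ids, cell_ids))
  da <- mo
  for (i in seq_len(n_seed)) {
    mo[i, ] <- count_on(track_outputs[[i]]$mother != 0)
    da[i, ] <- count_on(track_outputs[[i]]$daughter != 0)
  }
  areas <- as.integer(table(factor(labeled_seg[labeled_seg > 0],
                                   levels = cell_ids)))
  structure(list(mother = mo, daughter = da, cell_areas = areas,
                 seed_ids = seed_ids, cell_ids = cell_ids),
            class = "mm_scores")
}

#' Resolve a score matrix into frame-to-frame assignments
#'
#' Selects the set of links (each new cell receives at most one; each seed
#' keeps at most one mother-continuation and at most one daughter link) that
#' maximizes the total pixel overlap, via exact branch-and-bound search over
#' the (small) per-chamber score matrix.  Conflicts where two seeds give a
#' new cell exactly the same top attribution score are discarded up front:
#' the contested cell becomes a "new" cell that starts its own lineage tree.
#' A link is only eligible when the seed's combined mother+daughter overlap
#' covers at least `min_overlap` of the new cell's area; a tie between a
#' seed's own mother and daughter channels is broken toward the
#' mother-continuation.
#'
#' @param scores an `mm_scores` from [attribute_scores()].
#' @param min_overlap minimum combined overlap fraction of the new cell's
#'   area for any link (default 0.5).
#' @return data.frame with columns `seed`, `cell`, `type`
#'   (`"mother"`/`"daughter"`), `overlap`; attribute `roots` lists new cells
#'   that start a new lineage.
#' @export
resolve_assignments <- function(scores, min_overlap = 0.5) {
  ns <- length(scores$seed_ids); nc <- length(scores$cell_ids)
  empty <- data.frame(seed = character(0), cell = character(0),
                      type = character(0), overlap = integer(0),
                      stringsAsFactors = FALSE)
  if (nc == 0) { attr(empty, "roots") <- character(0); return(empty) }

  combined <- scores$mother + scores$daughter
  eligible <- combined >= matrix(min_overlap * scores$cell_areas,
                                 ns, nc, byrow = TRUE)

  # candidate options per cell: list of (seed index, type, score), in the
  # canonical order score desc, mother first, seed asc
  opts <- vector("list", nc)
  roots <- logical(nc)
  for (j in seq_len(nc)) {
    cand <- list()
    for (i in seq_len(ns)) {
      if (!eligible[i, j]) next
      if (scores$mother[i, j] > 0)
        cand[[length(cand) + 1]] <- list(i = i, type = "mother",
                                         s = scores$mother[i, j])
      if (scores$daughter[i, j] > 0)
        cand[[length(cand) + 1]] <- list(i = i, type = "daughter",
                                         s = scores$daughter[i, j])
    }
    if (length(cand) == 0) { roots[j] <- TRUE; next }
    # conflict rule: exactly tied top scores from different seeds
    per_seed_top <- tapply(vapply(cand, `[[`, numeric(1), "s"),
                           vapply(cand, `[[`, numeric(1), "i"), max)
    top <- max(per_seed_top)
    if (sum(per_seed_top == top) >= 2) { roots[j] <- TRUE; next }
    o <- order(-vapply(cand, `[[`, numeric(1), "s"),
               vapply(cand, function(x) x$type != "mother", logical(1)),
               vapply(cand, `[[`, numeric(1), "i"))
    opts[[j]] <- cand[o]
  }

  live <- which(!roots)
  best <- list(total = -1, choice = NULL)
  max_opt <- vapply(live, function(j) opts[[j]][[1]]$s, numeric(1))
  suffix_max <- rev(cumsum(rev(max_opt)))

  used_m <- logical(ns); used_d <- logical(ns)
  choice <- integer(length(live))   # option index per live cell, 0 = root
  recurse <- function(k, total) {
    if (k > length(live)) {
      if (total > best$total) best <<- list(total = total, choice = choice)
      return()
    }
    if (total + suffix_max[k] <= best$total) return()
    j <- live[k]
    for (oi in seq_along(opts[[j]])) {
      op <- opts[[j]][[oi]]
      if (op$type == "mother") {
        if (used_m[op$i]) next
        used_m[op$i] <<- TRUE
        choice[k] <<- oi
        recurse(k + 1, total + op$s)
        used_m[op$i] <<- FALSE
      } else {
        if (used_d[op$i]) next
        used_d[op$i] <<- TRUE
        choice[k] <<- oi
        recurse(k + 1, total + op$s)
        used_d[op$i] <<- FALSE
      }
    }
    choice[k] <<- 0L
    recurse(k + 1, total)
  }
  recurse(1, 0)

  links <- empty
  if (!is.null(best$choice)) for (k in seq_along(live)) {
    oi <- best$choice[k]
    if (oi == 0) next
    op <- opts[[live[k]]][[oi]]
    links <- rbind(links, data.frame(
      seed = scores$seed_ids[op$i], cell = scores$cell_ids[live[k]],
      type = op$type, overlap = op$s, stringsAsFactors = FALSE))
  }
  linked <- as.character(links$cell)
  attr(links, "roots") <-
    setdiff(as.character(scores$cell_ids), linked)
  attr(links, "total") <- max(best$total, 0)
  links
}

#' Assemble per-frame assignments into a lineage tree
#'
#' Creates, extends, and terminates cell tracks: mother-continuation links
#' extend a track into the next frame, daughter links open a new track with
#' `mother_id` set and the division frame recorded, unlinked new cells
#' become lineage roots, and tracks that end before the last frame are
#' marked as flushed out.
#'
#' @param assignments list of length `n_frames - 1`; element `t` is the
#'   link data.frame from [resolve_assignments()] between frames `t` and
#'   `t + 1`, with `seed` / `cell` referring to labels of the respective
#'   labelled masks.
#' @param labeled_movie list of labelled masks, one per frame.
#' @return an `mm_lineage`: named list of tracks (`cell_id`, `mother_id`,
#'   `first_frame`, `last_frame`, `daughter_ids`, `division_frames`,
#'   `exit_reason`, `regions` = per-frame pixel-index sets), plus `dim` and
#'   `n_frames`.
#' @export
assemble_lineage <- function(assignments, labeled_movie) {
  n_frames <- length(labeled_movie)
  stopifnot(length(assignments) == n_frames - 1)
  dims <- dim(labeled_movie[[1]])
  tracks <- list()
  next_id <- 1L
  region_of <- function(t, label) {
    idx <- which(labeled_movie[[t]] == as.integer(label))
    if (length(idx) == 0)
      stop(sprintf("assignment references nonexistent region %s at frame %d",
                   label, t))
    idx
  }
  new_track <- function(t, label, mother_id = NA_integer_) {
    id <- next_id; next_id <<- next_id + 1L
    regions <- vector("list", n_frames)
    regions[[t]] <- region_of(t, label)
    tracks[[as.character(id)]] <<- list(
      cell_id = id, mother_id = mother_id, first_frame = t, last_frame = t,
      daughter_ids = integer(0), division_frames = integer(0),
      exit_reason = NA_character_, regions = regions)
    id
  }
  # frame 1: every labelled region roots a track
  lab1 <- sort(unique(labeled_movie[[1]][labeled_movie[[1]] > 0]))
  label_track <- new.env(parent = emptyenv())
  for (l in lab1) assign(as.character(l), new_track(1L, l), label_track)

  for (t in seq_len(n_frames - 1)) {
    a <- assignments[[t]]
    next_map <- new.env(parent = emptyenv())
    extended <- character(0)
    if (nrow(a)) for (r in seq_len(nrow(a))) {
      seed_lab <- as.character(a$seed[r]); cell_lab <- as.character(a$cell[r])
      tid <- get(seed_lab, envir = label_track)
      key <- as.character(tid)
      if (a$type[r] == "mother") {
        tracks[[key]]$regions[[t + 1]] <- region_of(t + 1, cell_lab)
        tracks[[key]]$last_frame <- t + 1L
        assign(cell_lab, tid, next_map)
        extended <- c(extended, key)
      } else {
        did <- new_track(t + 1L, cell_lab, mother_id = tid)
        tracks[[key]]$daughter_ids <- c(tracks[[key]]$daughter_ids, did)
        tracks[[key]]$division_frames <-
          c(tracks[[key]]$division_frames, t + 1L)
        assign(cell_lab, did, next_map)
      }
    }
    # unlinked new cells become roots
    labs <- sort(unique(labeled_movie[[t + 1]][labeled_movie[[t + 1]] > 0]))
    for (l in as.character(labs))
      if (!exists(l, envir = next_map, inherits = FALSE))
        assign(l, new_track(t + 1L, as.integer(l)), next_map)
    # seeds without continuation terminate at t
    for (seed_lab in ls(label_track)) {
      tid <- get(seed_lab, envir = label_track)
      key <- as.character(tid)
      if (!(key %in% extended) && is.na(tracks[[key]]$exit_reason))
        tracks[[key]]$exit_reason <- "flushed"
    }
    label_track <- next_map
  }
  for (key in names(tracks))
    if (is.na(tracks[[key]]$exit_reason))
      tracks[[key]]$exit_reason <-
        if (tracks[[key]]$last_frame == n_frames) "movie_end" else "flushed"
  structure(list(tracks = tracks, dim = dims, n_frames = n_frames),
            class = "mm_lineage")
}

#' @export
print.mm_lineage <- function(x, ...) {
  nd <- sum(vapply(x$tracks, function(tr) length(tr$daughter_ids),
                   integer(1)))
  cat(sprintf("<mm_lineage> %d tracks, %d divisions, %d frames (%dx%d)\n",
              length(x$tracks), nd, x$n_frames, x$dim[1], x$dim[2]))
  invisible(x)
}

#' Track a segmented movie with the tracking network
#'
#' For every frame pair, runs [track_cell()] on each segmented cell of the
#' earlier frame, scores and resolves the assignments, and assembles the
#' lineage tree.
#'
#' @param net trained tracking `unet`.
#' @param images list of transmitted-light matrices.
#' @param seg_masks list of binary or labelled segmentation masks.
#' @param min_overlap passed to [resolve_assignments()].
#' @return an `mm_lineage`.
#' @export
track_movie <- function(net, images, seg_masks, min_overlap = 0.5) {
  n <- length(images)
  stopifnot(length(seg_masks) == n)
  labeled <- lapply(seg_masks, function(m)
    if (max(m) > 1) m else label_components(m))
  assignments <- vector("list", max(n - 1, 0))
  for (t in seq_len(n - 1)) {
    labs <- sort(unique(labeled[[t]][labeled[[t]] > 0]))
    outs <- lapply(labs, function(l)
      track_cell(net, images[[t]], labeled[[t]] == l, images[[t + 1]],
                 labeled[[t + 1]] > 0))
    names(outs) <- labs
    sc <- attribute_scores(outs, labeled[[t + 1]])
    assignments[[t]] <- resolve_assignments(sc, min_overlap)
  }
  assemble_lineage(assignments, labeled)
}

#' Render per-frame labelled masks from a lineage
#'
#' Labels are the track `cell_id`s.
#' @param lineage an `mm_lineage`.
#' @return list of integer matrices.
#' @export
lineage_masks <- function(lineage) {
  lapply(seq_len(lineage$n_frames), function(t) {
    m <- matrix(0L, lineage$dim[1], lineage$dim[2])
    for (tr in lineage$tracks)
      if (!is.null(tr$regions[[t]])) m[tr$regions[[t]]] <- tr$cell_id
    m
  })
}

#' Serialize a lineage to JSON (per-frame run-length encoded regions)
#' @param lineage an `mm_lineage`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lineage_json <- function(lineage, path) {
  tracks <- lapply(unname(lineage$tracks), function(tr) {
    frames <- which(!vapply(tr$regions, is.null, logical(1)))
    list(cell_id = tr$cell_id,
         mother_id = if (is.na(tr$mother_id)) NULL else tr$mother_id,
         first_frame = tr$first_frame, last_frame = tr$last_frame,
         daughter_ids = as.integer(tr$daughter_ids),
         division_frames = as.integer(tr$division_frames),
         exit_reason = tr$exit_reason,
         regions = lapply(frames, function(t)
           c(list(frame = t), rle_region(tr$regions[[t]]))))
  })
  jsonlite::write_json(list(dim = as.integer(lineage$dim),
                            n_frames = lineage$n_frames, tracks = tracks),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lineage written by [write_lineage_json()]
#' @param path JSON file.
#' @return an `mm_lineage`.
#' @export
read_lineage_json <- function(path) {
  j <- jsonlite::read_json(path)
  n_frames <- j$n_frames
  tracks <- list()
  for (tr in j$tracks) {
    regions <- vector("list", n_frames)
    for (rg in tr$regions)
      regions[[rg$frame]] <- rle_decode(list(
        start = unlist(rg$start), length = unlist(rg$length)))
    tracks[[as.character(tr$cell_id)]] <- list(
      cell_id = as.integer(tr$cell_id),
      mother_id = if (length(unlist(tr$mother_id)) == 0) NA_integer_
                  else as.integer(tr$mother_id),
      first_frame = tr$first_frame, last_frame = tr$last_frame,
      daughter_ids = as.integer(unlist(tr$daughter_ids)),
      division_frames = as.integer(unlist(tr$division_frames)),
      exit_reason = tr$exit_reason, regions = regions)
  }
  structure(list(tracks = tracks, dim = as.integer(unlist(j$dim)),
                 n_frames = n_frames), class = "mm_lineage")
}
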
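#' Evaluation configuration
#'
#' Rules for scoring predicted segmentation and lineages against ground
#' truth: a predicted cell is attributed to a ground-truth cell when they
#' overlap over at least `overlap_fraction` of the predicted cell's surface;
#' spurious or missing cells inside the `bottom_margin` pixel rows at the
#' open chamber end are waived (cells being flushed out are arbitrary to
#' call); and splitting/merging within `division_tolerance` frames of a true
#' division is not counted as an error (the exact division frame is
#' arbitrary to one frame).
#'
#' @param overlap_fraction attribution threshold (default 0.90).
#' @param bottom_margin waiver margin at the open end, pixels (default 5).
#' @param division_tolerance frames (default 1).
#' @return an `eval_config` list.
#' @export
eval_config <- function(overlap_fraction = 0.90, bottom_margin = 5,
                        division_tolerance = 1) {
  stopifnot(overlap_fraction > 0, overlap_fraction <= 1, bottom_margin >= 0,
            division_tolerance >= 0)
  structure(list(overlap_fraction = overlap_fraction,
                 bottom_margin = as.integer(bottom_margin),
                 division_tolerance = as.integer(division_tolerance)),
            class = "eval_config")
}

#' Attribute predicted cells to ground-truth cells
#'
#' A predicted cell is matched to the ground-truth cell containing at least
#' `overlap_fraction` of its own area.  Unattributed cells on both sides are
#' included in the table.
#'
#' @param pred_labeled,gt_labeled labelled matrices of the same shape.
#' @param config an [eval_config()].
#' @return data.frame: `pred_label`, `area`, `gt_label` (`NA` when
#'   unattributed), `overlap`; attribute `unmatched_gt` lists ground-truth
#'   labels that received no attribution.
#' @export
match_to_groundtruth <- function(pred_labeled, gt_labeled,
                                 config = eval_config()) {
  stopifnot(all(dim(pred_labeled) == dim(gt_labeled)))
  ov <- overlap_counts(pred_labeled, gt_labeled)
  pred_ids <- sort(unique(pred_labeled[pred_labeled > 0]))
  gt_ids <- sort(unique(gt_labeled[gt_labeled > 0]))
  areas <- as.integer(table(factor(pred_labeled[pred_labeled > 0],
                                   levels = pred_ids)))
  tab <- data.frame(pred_label = integer(0), area = integer(0),
                    gt_label = integer(0), overlap = integer(0))
  for (k in seq_along(pred_ids)) {
    row <- ov[as.character(pred_ids[k]), , drop = TRUE]
    best <- if (length(row)) which.max(row) else integer(0)
    matched <- length(best) > 0 &&
      row[best] >= config$overlap_fraction * areas[k]
    tab <- rbind(tab, data.frame(
      pred_label = pred_ids[k], area = areas[k],
      gt_label = if (matched) gt_ids[best] else NA_integer_,
      overlap = if (length(best)) unname(row[best]) else 0L))
  }
  attr(tab, "unmatched_gt") <- setdiff(gt_ids, tab$gt_label[!is.na(tab$gt_label)])
  tab
}

# does labelled cell `label` at frame t split into >= 2 cells within `tol`
# frames?  A frame-t+k cell is a successor when the majority of its area
# lies on the frame-t region of `label`.
divides_within <- function(movie, t, label, tol) {
  region <- movie[[t]] == label
  for (k in seq_len(tol)) {
    if (t + k > length(movie)) break
    nxt <- movie[[t + k]]
    ids <- sort(unique(nxt[nxt > 0]))
    succ <- 0
    for (id in ids) {
      a <- sum(nxt == id)
      if (sum(nxt == id & region) > 0.5 * a) succ <- succ + 1
    }
    if (succ >= 2) return(TRUE)
    # follow the (single) successor region for the next step
    region <- successor_region(movie, t + k - 1, region, nxt)
    if (!any(region)) break
  }
  FALSE
}

successor_region <- function(movie, t, region, nxt) {
  ids <- sort(unique(nxt[nxt > 0]))
  out <- matrix(FALSE, nrow(nxt), ncol(nxt))
  for (id in ids) {
    a <- sum(nxt == id)
    if (sum(nxt == id & region) > 0.5 * a) out <- out | (nxt == id)
  }
  out
}

in_bottom_margin <- function(labeled, label, margin) {
  if (margin == 0) return(FALSE)
  H <- nrow(labeled)
  rows <- ((which(labeled == label) - 1) %% H) + 1
  any(rows > H - margin)
}

#' Count segmentation errors over a movie
#'
#' Per frame: two or more predicted cells attributed to one ground-truth
#' cell is an over-segmentation unless the ground-truth cell divides within
#' the division tolerance; one predicted cell covering two or more
#' ground-truth cells (each attributed to it by at least the overlap
#' fraction of the ground-truth cell's area) is an under-segmentation unless
#' the predicted cell divides within the tolerance; remaining unattributed
#' predicted cells are false positives and unattributed ground-truth cells
#' are false negatives, each waived inside the bottom margin.
#'
#' @param pred_movie,gt_movie lists of labelled (or binary) masks.
#' @param config an [eval_config()].
#' @return an `mm_eval_report`: `counts`, `denominators`
#'   (`cells_evaluated` = total ground-truth cells), and a `records`
#'   data.frame (frame, category, labels).
#' @export
segmentation_errors <- function(pred_movie, gt_movie,
                                config = eval_config()) {
  stopifnot(length(pred_movie) == length(gt_movie))
  pred_movie <- lapply(pred_movie, function(m)
    if (max(m) > 1) m else label_components(m))
  gt_movie <- lapply(gt_movie, function(m)
    if (max(m) > 1) m else label_components(m))
  counts <- c(over_segmentation = 0L, under_segmentation = 0L,
              false_positive = 0L, false_negative = 0L)
  records <- data.frame(frame = integer(0), category = character(0),
                        pred_label = integer(0), gt_label = integer(0))
  n_gt_cells <- 0L
  rec <- function(t, cat, p = NA_integer_, g = NA_integer_) {
    counts[cat] <<- counts[cat] + 1L
    records <<- rbind(records, data.frame(frame = t, category = cat,
                                          pred_label = p, gt_label = g))
  }
  for (t in seq_along(gt_movie)) {
    pred <- pred_movie[[t]]; gt <- gt_movie[[t]]
    gt_ids <- sort(unique(gt[gt > 0]))
    n_gt_cells <- n_gt_cells + length(gt_ids)
    fwd <- match_to_groundtruth(pred, gt, config)          # pred -> gt
    bwd <- match_to_groundtruth(gt, pred, config)          # gt -> pred
    # over-segmentation: >= 2 preds on one gt
    over_gt <- integer(0)
    if (nrow(fwd)) {
      hit <- table(fwd$gt_label[!is.na(fwd$gt_label)])
      for (g in as.integer(names(hit)[hit >= 2])) {
        over_gt <- c(over_gt, g)
        if (!divides_within(gt_movie, t, g, config$division_tolerance))
          rec(t, "over_segmentation", g = g)
      }
    }
    # under-segmentation: >= 2 gts on one pred
    under_pred <- integer(0)
    if (nrow(bwd)) {
      hit <- table(bwd$gt_label[!is.na(bwd$gt_label)])   # here gt_label = pred id
      for (p in as.integer(names(hit)[hit >= 2])) {
        under_pred <- c(under_pred, p)
        if (!divides_within(pred_movie, t, p, config$division_tolerance))
          rec(t, "under_segmentation", p = p)
      }
    }
    # false positives: unattributed preds not explained by under-segmentation
    for (k in seq_len(nrow(fwd))) {
      if (!is.na(fwd$gt_label[k]) || fwd$pred_label[k] %in% under_pred) next
      if (in_bottom_margin(pred, fwd$pred_label[k], config$bottom_margin))
        next
      rec(t, "false_positive", p = fwd$pred_label[k])
    }
    # false negatives: gt cells with no attribution, not over-segmented
    attributed_gt <- fwd$gt_label[!is.na(fwd$gt_label)]
    for (g in gt_ids) {
      if (g %in% attributed_gt || g %in% over_gt) next
      if (g %in% bwd$pred_label[!is.na(bwd$gt_label) &
                                bwd$gt_label %in% under_pred]) next
      if (in_bottom_margin(gt, g, config$bottom_margin)) next
      rec(t, "false_negative", g = g)
    }
  }
  structure(list(counts = counts,
                 denominators = c(cells_evaluated = n_gt_cells),
                 records = records, config = config),
            class = "mm_eval_report")
}

#' @export
print.mm_eval_report <- function(x, ...) {
  cat("<mm_eval_report>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-20s %d\n", nm, x$counts[nm]))
  cat(sprintf("  cells evaluated      %d\n", x$denominators["cells_evaluated"]))
  cat(sprintf("  error rate           %.2f%%\n",
              error_rate(sum(x$counts), x$denominators["cells_evaluated"])))
  invisible(x)
}

#' Count tracking errors between two lineages
#'
#' Each (cell, frame -> frame+1) transition of the ground truth is a
#' tracking event.  The predicted cell matched to the ground-truth cell must
#' designate the same successor cells (continuation, plus daughter on
#' division).  Events tied to segmentation errors, to unmatched cells, or to
#' divisions detected at a different frame than the ground truth are
#' excluded from the denominator rather than counted as errors.
#'
#' @param pred_lineage,gt_lineage `mm_lineage` objects on the same movie.
#' @param seg_report optional `mm_eval_report` from [segmentation_errors()];
#'   its error records extend the exclusion set.
#' @param config an [eval_config()].
#' @return list: `errors`, `events` (denominator), `excluded`, and a
#'   `records` data.frame.
#' @export
tracking_errors <- function(pred_lineage, gt_lineage, seg_report = NULL,
                            config = eval_config()) {
  pm <- lineage_masks(pred_lineage)
  gm <- lineage_masks(gt_lineage)
  n <- length(gm)
  errors <- 0L; events <- 0L; excluded <- 0L
  records <- data.frame(frame = integer(0), gt_cell = integer(0),
                        outcome = character(0))
  # per-frame gt -> pred matching (by the attribution rule, both directions
  # must agree for a confident identity)
  match_at <- vector("list", n)
  for (t in seq_len(n)) {
    fwd <- match_to_groundtruth(pm[[t]], gm[[t]], config)
    g2p <- stats::setNames(fwd$pred_label, fwd$gt_label)[!is.na(fwd$gt_label)]
    match_at[[t]] <- g2p
  }
  seg_bad <- function(frames, gt_label, pred_label) {
    if (is.null(seg_report)) return(FALSE)
    r <- seg_report$records
    any(r$frame %in% frames &
          ((!is.na(r$gt_label) & r$gt_label %in% gt_label) |
             (!is.na(r$pred_label) & r$pred_label %in% pred_label)))
  }
  gt_tracks <- gt_lineage$tracks
  succ_of <- function(lin, t) {
    # map: cell_id alive at t -> list(cont = cell_id or NA, dau = cell_id or NA)
    out <- list()
    for (tr in lin$tracks) {
      if (is.null(tr$regions[[t]])) next
      cont <- if (t + 1 <= lin$n_frames && !is.null(tr$regions[[t + 1]]))
        tr$cell_id else NA_integer_
      dau <- NA_integer_
      dd <- tr$daughter_ids[vapply(tr$daughter_ids, function(d)
        lin$tracks[[as.character(d)]]$first_frame == t + 1, logical(1))]
      if (length(dd) == 1) dau <- dd
      out[[as.character(tr$cell_id)]] <- list(cont = cont, dau = dau)
    }
    out
  }
  for (t in seq_len(n - 1)) {
    gs <- succ_of(gt_lineage, t)
    ps <- succ_of(pred_lineage, t)
    g2p_t <- match_at[[t]]; g2p_t1 <- match_at[[t + 1]]
    for (gid in names(gs)) {
      s <- gs[[gid]]
      if (is.na(s$cont) && is.na(s$dau)) next   # flushed: no event
      events <- events + 1L
      pid <- g2p_t[gid]
      gt_next <- c(s$cont, s$dau)
      excl <- FALSE
      if (is.na(pid)) excl <- TRUE
      if (!excl && seg_bad(c(t, t + 1),
                           c(as.integer(gid), gt_next[!is.na(gt_next)]),
                           as.integer(pid)))
        excl <- TRUE
      if (!excl) {
        p <- ps[[as.character(pid)]]
        if (is.null(p)) { excl <- TRUE }
        else {
          gt_divided <- !is.na(s$dau)
          pred_divided <- !is.na(p$dau)
          if (gt_divided != pred_divided) excl <- TRUE   # division timing
        }
      }
      if (excl) {
        excluded <- excluded + 1L
        events <- events - 1L
        records <- rbind(records, data.frame(frame = t,
                                             gt_cell = as.integer(gid),
                                             outcome = "excluded"))
        next
      }
      # compare successors through the frame t+1 matching
      map_succ <- function(cid) {
        if (is.na(cid)) return(NA_integer_)
        hit <- names(g2p_t1)[g2p_t1 == cid]
        if (length(hit) == 1) as.integer(hit) else NA_integer_
      }
      pred_cont_gt <- map_succ(ps[[as.character(pid)]]$cont)
      pred_dau_gt <- map_succ(ps[[as.character(pid)]]$dau)
      ok <- identical(pred_cont_gt, as.integer(ifelse(is.na(s$cont),
                                                      NA, s$cont))) &&
        identical(pred_dau_gt, as.integer(ifelse(is.na(s$dau), NA, s$dau)))
      if (!ok) {
        errors <- errors + 1L
        records <- rbind(records, data.frame(frame = t,
                                             gt_cell = as.integer(gid),
                                             outcome = "error"))
      }
    }
  }
  list(errors = errors, events = events, excluded = excluded,
       records = records)
}

#' Error rate as a percentage
#'
#' `100 * errors / total`, rounded half-up to two decimals — the reporting
#' convention for segmentation and tracking error rates.
#'
#' @param errors,total non-negative counts; `total > 0`.
#' @return percentage (numeric).
#' @export
error_rate <- function(errors, total) {
  if (total <= 0) stop("undefined error rate: total must be positive")
  round_half_up(100 * errors / total, 2)
}

#' Pixel-level disagreement between two masks
#'
#' `100 * disagreeing pixels / denominator pixels`; the denominator is the
#' whole image by default, or the union of both foregrounds.
#'
#' @param pred_mask,gt_mask binary matrices of identical shape.
#' @param denominator `"image"` or `"union"`.
#' @return percentage.
#' @export
pixel_error <- function(pred_mask, gt_mask,
                        denominator = c("image", "union")) {
  denominator <- match.arg(denominator)
  stopifnot(all(dim(pred_mask) == dim(gt_mask)))
  dis <- sum((pred_mask != 0) != (gt_mask != 0))
  den <- if (denominator == "image") length(pred_mask)
         else sum(pred_mask != 0 | gt_mask != 0)
  if (den == 0) return(0)
  100 * dis / den
}

#' Write an evaluation report as JSON plus a text table
#' @param report an `mm_eval_report`.
#' @param path output JSON path (a `.txt` table is written alongside).
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(counts = as.list(report$counts),
                            denominators = as.list(report$denominators),
                            records = report$records),
                       path, auto_unbox = TRUE, digits = NA)
  txt <- c(sprintf("%-22s %s", "category", "count"),
           sprintf("%-22s %d", names(report$counts), report$counts),
           sprintf("%-22s %d", "cells evaluated",
                   report$denominators["cells_evaluated"]),
           sprintf("%-22s %.2f%%", "error rate",
                   error_rate(sum(report$counts),
                              report$denominators["cells_evaluated"])))
  writeLines(txt, paste0(sub("\\.json$", "", path), ".txt"))
  invisible(path)
}
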
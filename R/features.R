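#' Morphology of a cell region
#'
#' Area is the pixel count; length is the extent along the chamber axis
#' (row axis): `max row - min row + 1`.  Cells in the chamber are axially
#' constrained, which makes the axial extent the natural length measure.
#'
#' @param region pixel index vector (column-major linear indices).
#' @param dim image dimensions `c(H, W)`.
#' @return list with `length` (px) and `area` (px^2).
#' @export
cell_morphology <- function(region, dim) {
  if (length(region) == 0) stop("empty region")
  rows <- (region - 1) %% dim[1] + 1
  list(length = max(rows) - min(rows) + 1L, area = length(region))
}

#' Mean fluorescence over a cell region
#' @param region pixel index vector.
#' @param fluo_image fluorescence matrix.
#' @return scalar mean intensity (a.u.).
#' @export
mean_fluorescence <- function(region, fluo_image) {
  if (length(region) == 0) stop("empty region")
  mean(fluo_image[region])
}

#' Per-interval exponential growth rate
#'
#' `rate(t) = (ln L(t+1) - ln L(t)) / dt` within a cell cycle; intervals
#' spanning a division are excluded (returned as `NA`).
#'
#' @param length_series positive numeric vector, one value per frame.
#' @param division_frames frames (indices into the series) at which a
#'   division occurred (the daughter configuration is in place at that
#'   frame, so the interval ending there is excluded).
#' @param dt frame interval in minutes.
#' @return numeric vector of length `length(length_series) - 1` (1/min).
#' @export
growth_rate <- function(length_series, division_frames = integer(0), dt = 5) {
  if (any(length_series <= 0)) stop("non-positive length")
  n <- length(length_series)
  if (n < 2) return(numeric(0))
  r <- diff(log(length_series)) / dt
  spans <- division_frames[division_frames >= 2 & division_frames <= n] - 1
  r[spans] <- NA
  r
}

#' Per-cycle means of a signal
#'
#' Splits a track's per-frame signal at its division frames and returns the
#' mean over each complete cycle (division to division; the interval from an
#' observed birth to the first division also counts as complete).  The
#' trailing, unfinished interval is never included.
#'
#' @param signal numeric vector aligned to `frames`.
#' @param frames frame numbers of `signal`.
#' @param division_frames frames at which the track divided (the new cycle
#'   starts at the division frame).
#' @param birth_observed whether the first frame is a birth (daughter track)
#'   rather than the movie start (root track, first cycle discarded).
#' @return numeric vector of cycle means (possibly empty).
#' @export
cycle_means <- function(signal, frames, division_frames,
                        birth_observed = TRUE) {
  stopifnot(length(signal) == length(frames))
  division_frames <- sort(division_frames)
  bounds <- c(frames[1], division_frames)
  out <- numeric(0)
  for (k in seq_len(length(bounds) - 1)) {
    sel <- frames >= bounds[k] & frames < bounds[k + 1]
    if (!any(sel)) next
    if (k == 1 && !birth_observed) next
    out <- c(out, mean(signal[sel]))
  }
  out
}

#' Extract tidy per-cell per-frame time series from a lineage
#'
#' @param lineage an `mm_lineage`.
#' @param fluo optional list of fluorescence matrices (one per frame).
#' @param dt frame interval in minutes.
#' @return data.frame: `cell_id`, `frame`, `time_min`, `length`, `area`,
#'   and `fluo` when fluorescence images are supplied.
#' @export
cell_time_series <- function(lineage, fluo = NULL, dt = 5) {
  rows <- list()
  for (tr in lineage$tracks) {
    frames <- which(!vapply(tr$regions, is.null, logical(1)))
    for (t in frames) {
      m <- cell_morphology(tr$regions[[t]], lineage$dim)
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = tr$cell_id, frame = t, time_min = (t - 1) * dt,
        length = m$length, area = m$area,
        fluo = if (is.null(fluo)) NA_real_
               else mean_fluorescence(tr$regions[[t]], fluo[[t]]))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$cell_id, out$frame), ]
}

# cycle forest: one node per complete cell cycle, linked mother cycle ->
# the two post-division cycles (the continuing track's next cycle and the
# daughter track's first cycle).  Root tracks' first interval (birth
# unobserved) and trailing unfinished intervals are excluded as nodes but
# still anchor their children as forest roots.
cycle_forest <- function(lineage, series, signal = "fluo") {
  nodes <- list()
  # cycle key: (cell_id, index of the division that *ends* the cycle)
  for (tr in lineage$tracks) {
    dv <- sort(tr$division_frames)
    if (length(dv) == 0) next
    s <- series[series$cell_id == tr$cell_id, ]
    bounds <- c(tr$first_frame, dv)
    birth_observed <- !is.na(tr$mother_id)
    for (k in seq_len(length(bounds) - 1)) {
      if (k == 1 && !birth_observed) next
      sel <- s$frame >= bounds[k] & s$frame < bounds[k + 1]
      if (!any(sel)) next
      nodes[[paste(tr$cell_id, k, sep = ".")]] <- list(
        cell_id = tr$cell_id, k = k, end_div = bounds[k + 1],
        mean = mean(s[[signal]][sel]))
    }
  }
  # parent links: the cycle ending at division d of track T is the parent of
  # (a) T's cycle k+1 and (b) the first cycle of the daughter born at d
  parent <- character(0)
  for (tr in lineage$tracks) {
    dv <- sort(tr$division_frames)
    for (k in seq_along(dv)) {
      pk <- paste(tr$cell_id, k, sep = ".")
      if (!pk %in% names(nodes)) next
      ck <- paste(tr$cell_id, k + 1, sep = ".")
      if (ck %in% names(nodes)) parent[ck] <- pk
      dau <- tr$daughter_ids[vapply(tr$daughter_ids, function(d)
        lineage$tracks[[as.character(d)]]$first_frame == dv[k], logical(1))]
      if (length(dau) == 1) {
        dk <- paste(dau, 1, sep = ".")
        if (dk %in% names(nodes)) parent[dk] <- pk
      }
    }
  }
  list(nodes = nodes, parent = parent)
}

#' Correlation between ancestor and descendant cycle means
#'
#' Builds all (ancestor cycle, descendant cycle) pairs separated by `gap`
#' divisions — the ancestor cycle immediately precedes the divergence
#' division, the descendant cycle immediately follows its birth division —
#' and returns the Pearson correlation of the per-cycle mean signals.
#' With an AR(1)-heritable signal of inheritance coefficient `phi`, the
#' correlation decays as `phi^gap`.
#'
#' @param lineage an `mm_lineage`, or a list of them (one per chamber);
#'   pairs are pooled across chambers, which is how multi-chamber
#'   experiments are analyzed — a single chamber descends from one founder
#'   and per-chamber centering attenuates the correlation.
#' @param series tidy series from [cell_time_series()], or a list matching
#'   `lineage`.
#' @param gap generation gap: 1 (mother-daughter), 2, or 3.
#' @param signal column of `series` to average per cycle.
#' @return Pearson correlation coefficient; attribute `n_pairs`.
#' @export
generation_correlation <- function(lineage, series, gap = 1,
                                   signal = "fluo") {
  stopifnot(gap %in% 1:3)
  if (inherits(lineage, "mm_lineage")) {
    lineage <- list(lineage)
    series <- list(series)
  }
  anc <- descen <- numeric(0)
  for (i in seq_along(lineage)) {
    cf <- cycle_forest(lineage[[i]], series[[i]], signal)
    for (key in names(cf$nodes)) {
      up <- key
      ok <- TRUE
      for (g in seq_len(gap)) {
        up <- cf$parent[up]
        if (is.na(up) || is.null(up)) { ok <- FALSE; break }
      }
      if (!ok) next
      anc <- c(anc, cf$nodes[[up]]$mean)
      descen <- c(descen, cf$nodes[[key]]$mean)
    }
  }
  if (length(anc) < 3)
    stop("fewer than 3 ancestor-descendant pairs at this gap")
  r <- cor(anc, descen)
  attr(r, "n_pairs") <- length(anc)
  r
}

#' Normalized autocorrelation of a single-cell signal
#'
#' Auto-covariance of the mean-removed signal, normalized to the value at
#' zero lag: `rho(0) = 1`, `rho(k) = sum (x_t - xbar)(x_{t+k} - xbar) /
#' sum (x_t - xbar)^2`.
#'
#' @param series numeric vector (length >= 2, finite).
#' @param max_lag largest lag returned (default `length(series) - 1`).
#' @return numeric vector of `rho(0..max_lag)`, named by lag.
#' @export
autocorrelation <- function(series, max_lag = length(series) - 1) {
  n <- length(series)
  if (n < 2 || any(!is.finite(series))) stop("series too short or non-finite")
  x <- series - mean(series)
  v0 <- sum(x^2)
  if (v0 == 0) stop("zero-variance series: autocorrelation undefined")
  max_lag <- min(max_lag, n - 1)
  rho <- vapply(0:max_lag, function(k)
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / v0, numeric(1))
  names(rho) <- 0:max_lag
  rho
}

#' Write feature tables (per-frame and per-cycle CSVs)
#'
#' @param lineage an `mm_lineage`.
#' @param dir output directory.
#' @param fluo optional fluorescence frames.
#' @param dt frame interval (minutes).
#' @return the per-frame data.frame, invisibly.
#' @export
write_feature_tables <- function(lineage, dir, fluo = NULL, dt = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series <- cell_time_series(lineage, fluo = fluo, dt = dt)
  write.csv(series, file.path(dir, "cells_by_frame.csv"), row.names = FALSE)
  cyc <- list()
  for (tr in lineage$tracks) {
    s <- series[series$cell_id == tr$cell_id, ]
    if (nrow(s) == 0 || length(tr$division_frames) == 0) next
    for (sig in intersect(c("length", "fluo"), names(s))) {
      cm <- cycle_means(s[[sig]], s$frame, tr$division_frames,
                        birth_observed = !is.na(tr$mother_id))
      if (length(cm))
        cyc[[length(cyc) + 1]] <- data.frame(
          cell_id = tr$cell_id, cycle = seq_along(cm), signal = sig,
          mean = cm)
    }
  }
  if (length(cyc))
    write.csv(do.call(rbind, cyc), file.path(dir, "cells_by_cycle.csv"),
              row.names = FALSE)
  invisible(series)
}
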
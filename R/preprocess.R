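#' Locate growth chambers by template matching
#'
#' Cross-correlates an empty-chamber template against a full-field frame and
#' returns the chamber centers.  The correlation is zero-mean normalized
#' (ZNCC), which makes detection robust to global illumination offsets.
#' Peaks are selected greedily, highest correlation first, suppressing any
#' later peak closer than `min_separation` to an accepted one, and returned
#' ordered by column.
#'
#' @param frame numeric matrix, the full-field image.
#' @param template numeric matrix, strictly smaller than `frame` in both
#'   dimensions.
#' @param min_separation minimum Euclidean distance (pixels) between accepted
#'   peaks; defaults to 0.8 x template width.
#' @param threshold minimum normalized correlation for a peak (default 0.5).
#'   If no peak exceeds it an empty matrix is returned with a warning.
#' @return integer matrix with columns `row`, `col`: chamber centers
#'   (1-based pixel coordinates), ordered by column.
#' @export
detect_chambers <- function(frame, template, min_separation = NULL,
                            threshold = 0.5) {
  stopifnot(is.matrix(frame), is.matrix(template))
  if (!all(dim(template) < dim(frame)))
    stop("template must be strictly smaller than frame in both dimensions")
  if (!all(is.finite(frame)) || !all(is.finite(template)))
    stop("non-finite intensities")
  if (sd(frame) == 0 || sd(template) == 0)
    stop("degenerate input: constant frame or template")
  if (is.null(min_separation)) min_separation <- 0.8 * ncol(template)
  stopifnot(min_separation >= 1)

  cc <- zncc_valid(frame, template)
  cand <- which(cc > threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    warning("no correlation peak above threshold; no chambers detected")
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  ord <- order(cc[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  sel <- matrix(numeric(0), 0, 2)
  for (k in seq_len(nrow(cand))) {
    p <- cand[k, ]
    if (nrow(sel) == 0L ||
        all(sqrt((sel[, 1] - p[1])^2 + (sel[, 2] - p[2])^2) >= min_separation))
      sel <- rbind(sel, p)
  }
  centers <- cbind(row = sel[, 1] + floor(nrow(template) / 2),
                   col = sel[, 2] + floor(ncol(template) / 2))
  centers <- centers[order(centers[, "col"]), , drop = FALSE]
  storage.mode(centers) <- "integer"
  rownames(centers) <- NULL
  centers
}

# zero-mean normalized cross-correlation over all valid offsets, FFT-based
# numerator and integral-image local statistics.  Result (i, j) corresponds
# to the template placed with its top-left pixel at frame position (i, j).
zncc_valid <- function(frame, template) {
  H <- nrow(frame); W <- ncol(frame)
  h <- nrow(template); w <- ncol(template)
  t0 <- template - mean(template)
  st <- sqrt(sum(t0^2))

  # numerator via FFT: correlation = conv with the flipped template
  ph <- H + h - 1; pw <- W + w - 1
  fp <- matrix(0, ph, pw); fp[1:H, 1:W] <- frame
  tp <- matrix(0, ph, pw); tp[1:h, 1:w] <- t0[h:1, w:1]
  num_full <- Re(stats::fft(stats::fft(fp) * stats::fft(tp), inverse = TRUE)) / (ph * pw)
  num <- num_full[h:H, w:W, drop = FALSE]

  # local window sums via padded integral images
  s1 <- apply(apply(frame, 2, cumsum), 1, cumsum)    # transposed cumsum
  s1 <- t(s1); s2 <- apply(apply(frame^2, 2, cumsum), 1, cumsum); s2 <- t(s2)
  win_sum <- function(S) {
    Sp <- matrix(0, H + 1, W + 1); Sp[-1, -1] <- S
    i1 <- 1:(H - h + 1); j1 <- 1:(W - w + 1)
    Sp[i1 + h, j1 + w, drop = FALSE] - Sp[i1, j1 + w, drop = FALSE] -
      Sp[i1 + h, j1, drop = FALSE] + Sp[i1, j1, drop = FALSE]
  }
  f1 <- win_sum(s1); f2 <- win_sum(s2)
  n <- h * w
  denom <- sqrt(pmax(f2 - f1^2 / n, 0)) * st
  out <- num / denom
  out[!is.finite(out) | denom < 1e-12] <- 0
  out
}

#' Estimate integer XY drift between two frames
#'
#' Finds the integer shift `(dy, dx)` within `max_shift` that maximizes the
#' normalized correlation between `frame` and `reference`, i.e. the shift
#' such that `frame` looks like `reference` translated by `(dy, dx)`.
#' Drift is estimated against the first frame of a movie (not chained
#' frame-to-frame) so that errors do not accumulate.
#'
#' @param frame,reference numeric matrices of identical shape.
#' @param max_shift maximum absolute shift searched, in pixels.
#' @return integer vector `c(dy, dx)`, with attributes `confidence` (peak
#'   correlation) and `boundary` (TRUE when the optimum lies on the search
#'   boundary, in which case a warning is raised).
#' @export
estimate_drift <- function(frame, reference, max_shift = 10) {
  stopifnot(all(dim(frame) == dim(reference)), max_shift >= 0)
  H <- nrow(frame); W <- ncol(frame)
  best <- c(0, 0); best_cor <- -Inf
  for (dy in -max_shift:max_shift) {
    r1 <- max(1, 1 + dy):min(H, H + dy)
    r0 <- r1 - dy
    for (dx in -max_shift:max_shift) {
      c1 <- max(1, 1 + dx):min(W, W + dx)
      c0 <- c1 - dx
      a <- frame[r1, c1]; b <- reference[r0, c0]
      if (sd(a) == 0 || sd(b) == 0) next
      cc <- cor(as.vector(a), as.vector(b))
      if (cc > best_cor) { best_cor <- cc; best <- c(dy, dx) }
    }
  }
  boundary <- max_shift > 0 && any(abs(best) == max_shift)
  if (boundary)
    warning("drift estimate on search boundary; drift may be under-estimated")
  out <- as.integer(best)
  names(out) <- c("dy", "dx")
  attr(out, "confidence") <- if (is.finite(best_cor)) best_cor else 0
  attr(out, "boundary") <- boundary
  out
}

#' Crop fixed-size chamber images around detected centers
#'
#' Extracts one `crop_shape` crop per center, shifted by the current drift
#' estimate.  Crops extending past the frame edge are filled by edge
#' replication so all crops share an identical shape.
#'
#' @param frame numeric matrix.
#' @param centers matrix with columns `row`, `col` as returned by
#'   [detect_chambers()].
#' @param crop_shape integer `c(H, W)` of each crop (default `c(256, 32)`).
#' @param drift integer `c(dy, dx)` added to every center before cropping.
#' @return list of numeric `H x W` matrices, one per center.
#' @export
crop_chambers <- function(frame, centers, crop_shape = c(256, 32),
                          drift = c(0, 0)) {
  stopifnot(all(crop_shape >= 1))
  Hc <- crop_shape[1]; Wc <- crop_shape[2]
  H <- nrow(frame); W <- ncol(frame)
  lapply(seq_len(nrow(centers)), function(k) {
    r0 <- round(centers[k, 1] + drift[1]) - floor(Hc / 2)
    c0 <- round(centers[k, 2] + drift[2]) - floor(Wc / 2)
    rows <- pmin(pmax(r0 + seq_len(Hc) - 1, 1), H)
    cols <- pmin(pmax(c0 + seq_len(Wc) - 1, 1), W)
    frame[rows, cols, drop = FALSE]
  })
}

#' Build per-chamber image stacks from a full-field movie
#'
#' Detects chambers on the first frame, estimates per-frame drift against the
#' first frame, and crops a fixed-size stack per chamber.
#'
#' @param frames list of full-field matrices (time-ordered).
#' @param template empty-chamber template matrix.
#' @param crop_shape crop size `c(H, W)` per chamber.
#' @param max_shift drift search radius in pixels.
#' @param ... passed to [detect_chambers()].
#' @return list of chamber stacks; each has `frames` (list of crops),
#'   `chamber_id`, `center` and a `drift_trace` matrix (`dy`, `dx` per frame).
#' @export
build_chamber_stacks <- function(frames, template, crop_shape = c(256, 32),
                                 max_shift = 10, ...) {
  stopifnot(length(frames) >= 1)
  centers <- detect_chambers(frames[[1]], template, ...)
  drift <- t(vapply(seq_along(frames), function(t) {
    if (t == 1) c(dy = 0L, dx = 0L)
    else suppressWarnings(estimate_drift(frames[[t]], frames[[1]], max_shift))
  }, integer(2)))
  lapply(seq_len(nrow(centers)), function(k) {
    crops <- lapply(seq_along(frames), function(t)
      crop_chambers(frames[[t]], centers[k, , drop = FALSE], crop_shape,
                    drift[t, ])[[1]])
    structure(list(frames = crops, chamber_id = k,
                   center = centers[k, ], drift_trace = drift),
              class = "mm_chamber_stack")
  })
}

#' Read a (multi-page) TIFF stack as a list of matrices
#' @param path file path.
#' @return list of numeric matrices in `[0, 1]`.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p
  })
}

#' Write a list of matrices as a 16-bit multi-page TIFF
#' @param images list of numeric matrices in `[0, 1]`.
#' @param path output file path.
#' @export
write_image_stack <- function(images, path) {
  tiff::writeTIFF(lapply(images, clamp01), path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a chamber stack to disk (TIFF + JSON sidecar)
#'
#' @param stack an `mm_chamber_stack`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_chamber_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_stack(stack$frames,
                    file.path(dir, sprintf("chamber%03d.tif", stack$chamber_id)))
  side <- list(chamber_id = stack$chamber_id,
               center = as.integer(stack$center),
               drift_trace = unname(apply(stack$drift_trace, 1, as.integer,
                                          simplify = FALSE)))
  jsonlite::write_json(side, file.path(dir, sprintf("chamber%03d.json",
                                                    stack$chamber_id)),
                       auto_unbox = TRUE)
  invisible(dir)
}
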
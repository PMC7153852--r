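#' Simulation parameters for synthetic chamber movies
#'
#' The simulator emulates a one-end-closed mother-machine growth chamber:
#' rod-shaped cells stacked from the closed end (row 1) elongate
#' exponentially, divide when they reach an inherited length threshold, and
#' are pushed toward and eventually out of the open end (last row).  A
#' fluorescence channel carries a per-cycle expression level inherited
#' between generations as a stationary AR(1) process with coefficient `phi`,
#' so ancestor-descendant correlations decay as `phi^gap`.
#'
#' Default geometry follows the real device at 0.1 um/px: a 25 um chamber is
#' about 250 rows, cells are ~1.3 um wide, and frames are 5 minutes apart;
#' the default doubling time of ~40 min matches E. coli in glucose minimal
#' medium with amino acids at 37 C.
#'
#' @param chamber_height,chamber_width chamber crop size in pixels.
#' @param cell_width rod width in pixels (< `chamber_width`).
#' @param initial_length birth length of the founding cell, pixels.
#' @param growth_rate mean elongation rate (1/min); default `log(2)/40`.
#' @param growth_cv coefficient of variation of per-cycle elongation rates.
#' @param division_length mean division length threshold, pixels.
#' @param division_cv CV of the division threshold.
#' @param asymmetry_sd standard deviation of the division split fraction
#'   around 0.5 (truncated to `[0.35, 0.65]`).
#' @param phi fluorescence inheritance coefficient per generation (0..1).
#' @param fluor_mean,fluor_sd stationary mean and standard deviation of the
#'   per-cycle expression level (a.u., also the fluorescence image
#'   foreground intensity scale).
#' @param fluor_frame_noise per-frame fluctuation of the expressed level.
#' @param noise_sd additive image (photon) noise standard deviation.
#' @param psf_sigma Gaussian blur of the optics, pixels.
#' @param dt frame interval, minutes.
#' @param n_frames number of frames.
#' @param cell_gap background gap kept between stacked cells, pixels.
#' @return a `sim_params` list.
#' @export
sim_params <- function(chamber_height = 256, chamber_width = 32,
                       cell_width = 13, initial_length = 26,
                       growth_rate = log(2) / 40, growth_cv = 0.15,
                       division_length = 52, division_cv = 0.08,
                       asymmetry_sd = 0.04, phi = 0.8,
                       fluor_mean = 0.5, fluor_sd = 0.15,
                       fluor_frame_noise = 0.02,
                       noise_sd = 0.03, psf_sigma = 1, dt = 5,
                       n_frames = 30, cell_gap = 1) {
  stopifnot(cell_width < chamber_width, phi >= 0, phi <= 1,
            chamber_height > 0, initial_length > 0, division_length > 0,
            growth_rate >= 0, dt > 0, n_frames >= 1, cell_gap >= 1)
  structure(as.list(environment()), class = "sim_params")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

# draw a heritable per-cycle property as a stationary AR(1) step from the
# parent's value
inherit_ar1 <- function(parent, mean, sd, phi) {
  mean + phi * (parent - mean) + rnorm(1, 0, sd * sqrt(max(1 - phi^2, 0)))
}

#' Simulate chamber geometry and lineage ground truth
#'
#' Runs the growth/division/flush dynamics and returns the exact per-frame
#' rod geometry (real-valued tops and lengths), the true lineage tree and
#' per-cell properties.  Fully reproducible under a fixed seed.
#'
#' @param params a [sim_params()].
#' @param seed optional integer seed (applied with [set.seed()]).
#' @return an `mm_groundtruth` (without rendered frames; see
#'   [render_frames()]): `geometry` data.frame (frame, cell_id, top, length,
#'   growth_rate, fluor), `lineage` (an `mm_lineage` whose regions are the
#'   rasterized rods), `masks` (per-frame labelled matrices, labels =
#'   cell_id), and `params`.
#' @export
simulate_lineage <- function(params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  cells <- list(list(id = 1L, L = p$initial_length,
                     lambda = rtrunc_norm(1, p$growth_rate,
                                          p$growth_cv * p$growth_rate,
                                          0, 2 * p$growth_rate),
                     thr = rtrunc_norm(1, p$division_length,
                                       p$division_cv * p$division_length,
                                       p$initial_length * 1.2,
                                       2 * p$division_length),
                     fluor = rnorm(1, p$fluor_mean, p$fluor_sd)))
  next_id <- 2L
  meta <- list(`1` = list(cell_id = 1L, mother_id = NA_integer_,
                          first_frame = 1L, daughter_ids = integer(0),
                          division_frames = integer(0),
                          last_frame = 1L))
  geom <- list()
  record <- function(frame) {
    top <- 0
    for (c in cells) {
      geom[[length(geom) + 1]] <<- data.frame(
        frame = frame, cell_id = c$id, top = top, length = c$L,
        growth_rate = c$lambda, fluor = c$fluor)
      top <- top + ceiling(c$L) + p$cell_gap
    }
  }
  record(1L)
  for (t in seq_len(p$n_frames - 1L)) {
    frame <- t + 1L
    # grow
    cells <- lapply(cells, function(c) { c$L <- c$L * exp(c$lambda * p$dt); c })
    # divide
    new_cells <- list()
    for (c in cells) {
      if (c$L >= c$thr) {
        f <- rtrunc_norm(1, 0.5, p$asymmetry_sd, 0.35, 0.65)
        upper <- c; lower <- c
        upper$L <- f * c$L
        lower$L <- (1 - f) * c$L
        # both offspring start a new cycle: redraw rates/thresholds and
        # inherit expression
        for (nm in c("upper", "lower")) {
          x <- get(nm)
          x$lambda <- rtrunc_norm(1, p$growth_rate,
                                  p$growth_cv * p$growth_rate,
                                  0, 2 * p$growth_rate)
          x$thr <- rtrunc_norm(1, p$division_length,
                               p$division_cv * p$division_length,
                               p$initial_length * 1.2, 2 * p$division_length)
          x$fluor <- inherit_ar1(c$fluor, p$fluor_mean, p$fluor_sd, p$phi)
          assign(nm, x)
        }
        lower$id <- next_id; next_id <- next_id + 1L
        meta[[as.character(c$id)]]$daughter_ids <-
          c(meta[[as.character(c$id)]]$daughter_ids, lower$id)
        meta[[as.character(c$id)]]$division_frames <-
          c(meta[[as.character(c$id)]]$division_frames, frame)
        meta[[as.character(lower$id)]] <- list(
          cell_id = lower$id, mother_id = c$id, first_frame = frame,
          daughter_ids = integer(0), division_frames = integer(0),
          last_frame = frame)
        new_cells <- c(new_cells, list(upper), list(lower))
      } else new_cells <- c(new_cells, list(c))
    }
    cells <- new_cells
    if (length(cells) > 0) {
      tops <- cumsum(c(0, head(vapply(cells, function(c)
        ceiling(c$L) + p$cell_gap, numeric(1)), -1)))
      keep <- tops < p$chamber_height
      cells <- cells[keep]
    }
    for (c in cells) meta[[as.character(c$id)]]$last_frame <- frame
    record(frame)
  }
  geometry <- do.call(rbind, geom)
  masks <- rasterize_geometry(geometry, p)
  tracks <- list()
  for (m in meta) {
    regions <- vector("list", p$n_frames)
    for (t in m$first_frame:m$last_frame) {
      idx <- which(masks[[t]] == m$cell_id)
      if (length(idx)) regions[[t]] <- idx
    }
    # a cell can leave the raster (fully below the open end) before its
    # track formally ends; trim to rasterized frames
    present <- which(!vapply(regions, is.null, logical(1)))
    if (length(present) == 0) next
    tracks[[as.character(m$cell_id)]] <- list(
      cell_id = m$cell_id, mother_id = m$mother_id,
      first_frame = min(present), last_frame = max(present),
      daughter_ids = m$daughter_ids, division_frames = m$division_frames,
      exit_reason = if (max(present) == p$n_frames) "movie_end" else "flushed",
      regions = regions)
  }
  # a daughter flushed before it was ever rasterized has no track; drop the
  # dangling daughter link (the division itself still happened and stays in
  # division_frames so division-spanning intervals are excluded downstream)
  ids <- vapply(tracks, `[[`, integer(1), "cell_id")
  for (key in names(tracks))
    tracks[[key]]$daughter_ids <-
      tracks[[key]]$daughter_ids[tracks[[key]]$daughter_ids %in% ids]
  lineage <- structure(list(tracks = tracks,
                            dim = c(p$chamber_height, p$chamber_width),
                            n_frames = p$n_frames),
                       class = "mm_lineage")
  structure(list(params = p, geometry = geometry, masks = masks,
                 lineage = lineage, n_frames = p$n_frames,
                 dim = c(p$chamber_height, p$chamber_width)),
            class = "mm_groundtruth")
}

# rasterize rods as rounded-end capsules on the chamber axis
rasterize_geometry <- function(geometry, p) {
  H <- p$chamber_height; W <- p$chamber_width
  cx <- (W + 1) / 2
  hw <- p$cell_width / 2
  rowc <- matrix(seq_len(H), H, W)
  colc <- matrix(seq_len(W), H, W, byrow = TRUE)
  lapply(seq_len(p$n_frames), function(t) {
    m <- matrix(0L, H, W)
    g <- geometry[geometry$frame == t, , drop = FALSE]
    for (k in seq_len(nrow(g))) {
      top <- g$top[k] + 1          # 1-based row of the rod's upper end
      bot <- g$top[k] + g$length[k]
      if (top > H) next
      # capsule: distance to the axis segment between the two end centres
      a <- top + hw; b <- bot - hw
      if (b < a) { a <- (top + bot) / 2; b <- a }
      ry <- pmin(pmax(rowc, a), b)
      inside <- ((rowc - ry)^2 + (colc - cx)^2) <= hw^2 & rowc <= H
      m[inside] <- g$cell_id[k]
    }
    m
  })
}

#' Render transmitted-light and fluorescence frames for a simulation
#'
#' Transmitted channel: bright background (0.75) with dark rods (0.25),
#' blurred by the PSF and corrupted with Gaussian noise — the
#' phase-contrast-like appearance of bacteria in the device.  Fluorescence
#' channel: each rod glows at its cell's current expression level over a
#' dim background, with the same blur and noise.  The labelled masks stay
#' unblurred.
#'
#' @param gt an `mm_groundtruth` from [simulate_lineage()].
#' @param seed optional seed for the noise draw.
#' @return `gt` with a `frames` element: per frame, matrices `trans` and
#'   `fluo`.
#' @export
render_frames <- function(gt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- gt$params
  fr <- lapply(seq_len(gt$n_frames), function(t) {
    mask <- gt$masks[[t]]
    trans <- matrix(0.75, nrow(mask), ncol(mask))
    trans[mask > 0] <- 0.25
    fluo <- matrix(0.02, nrow(mask), ncol(mask))
    g <- gt$geometry[gt$geometry$frame == t, ]
    for (k in seq_len(nrow(g))) {
      lv <- g$fluor[k] + rnorm(1, 0, p$fluor_frame_noise)
      fluo[mask == g$cell_id[k]] <- max(lv, 0)
    }
    blur <- function(img) {
      if (p$psf_sigma > 0)
        img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                        sigma = p$psf_sigma))
      img
    }
    trans <- clamp01(blur(trans) + rnorm(length(trans), 0, p$noise_sd))
    fluo <- clamp01(blur(fluo) + rnorm(length(fluo), 0, p$noise_sd))
    list(trans = trans, fluo = fluo)
  })
  gt$frames <- fr
  gt
}

#' Simulate and render a complete synthetic movie
#' @inheritParams simulate_lineage
#' @return an `mm_groundtruth` with rendered `frames`.
#' @export
simulate_movie <- function(params = sim_params(), seed = NULL) {
  render_frames(simulate_lineage(params, seed))
}

#' Generate the standard fixture suite (easy / crowded / dim regimes)
#'
#' Three reproducible regimes exercised by the downstream modules: `easy`
#' (default signal-to-noise), `crowded` (faster growth, more frequent
#' divisions), and `dim` (low contrast, high noise).
#'
#' @param dir optional directory; when given, each movie is written as
#'   TIFF stacks plus ground-truth JSON.
#' @param seeds named integer seeds per regime.
#' @param base_params a [sim_params()] used as the template.
#' @return named list of rendered `mm_groundtruth` objects.
#' @export
make_fixture_suite <- function(dir = NULL,
                               seeds = c(easy = 101, crowded = 102,
                                         dim = 103),
                               base_params = sim_params()) {
  modify <- function(p, ...) {
    ch <- list(...)
    for (nm in names(ch)) p[[nm]] <- ch[[nm]]
    p
  }
  grids <- list(
    easy = base_params,
    crowded = modify(base_params, growth_rate = log(2) / 25,
                     n_frames = max(base_params$n_frames, 60)),
    dim = modify(base_params, noise_sd = 0.08))
  out <- lapply(names(grids), function(nm)
    simulate_movie(grids[[nm]], seed = seeds[[nm]]))
  names(out) <- names(grids)
  if (!is.null(dir)) {
    for (nm in names(out)) {
      sub <- file.path(dir, nm)
      dir.create(sub, recursive = TRUE, showWarnings = FALSE)
      gtm <- out[[nm]]
      write_image_stack(lapply(gtm$frames, `[[`, "trans"),
                        file.path(sub, "trans.tif"))
      write_image_stack(lapply(gtm$frames, `[[`, "fluo"),
                        file.path(sub, "fluo.tif"))
      write_image_stack(lapply(gtm$masks, function(m) m / max(1, max(m))),
                        file.path(sub, "masks.tif"))
      write_lineage_json(gtm$lineage, file.path(sub, "lineage.json"))
      jsonlite::write_json(unclass(gtm$params),
                           file.path(sub, "params.json"), auto_unbox = TRUE)
    }
  }
  out
}
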
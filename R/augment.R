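#' Augmentation configuration
#'
#' On-the-fly stochastic augmentation applied identically to every channel of
#' a training sample: standard geometric operations (shift, scale, rotation,
#' flip), a smooth elastic deformation, and two monotone intensity
#' remappings that emulate lamp-setting and chamber-axis illumination
#' variation between experiments.  Intensity operations apply only to
#' transmitted-light channels, never to masks or weight maps.
#'
#' @param shift_range maximum |shift| in pixels (applied per axis).
#' @param scale_range maximum relative scale change (0.1 = +/-10%).
#' @param rotation_range maximum |rotation| in degrees.
#' @param flip_h,flip_v enable random horizontal / vertical flips.
#' @param elastic_spacing coarse displacement-grid spacing in pixels.
#' @param elastic_sigma displacement standard deviation in pixels (0 disables).
#' @param pchip_knots number of knots of the random monotone intensity curves
#'   (>= 3).
#' @param histogram_distort_enabled,illumination_distort_enabled enable the
#'   two intensity operations; disabling them mirrors the ablation in which
#'   segmentation degrades without illumination augmentation.
#' @return an `augment_config` list.
#' @export
augment_config <- function(shift_range = 5, scale_range = 0.05,
                           rotation_range = 2, flip_h = TRUE, flip_v = FALSE,
                           elastic_spacing = 16, elastic_sigma = 1.5,
                           pchip_knots = 5,
                           histogram_distort_enabled = TRUE,
                           illumination_distort_enabled = TRUE) {
  stopifnot(shift_range >= 0, scale_range >= 0, rotation_range >= 0,
            elastic_spacing >= 2, elastic_sigma >= 0, pchip_knots >= 3)
  structure(as.list(environment()), class = "augment_config")
}

#' Random monotone intensity mapping (shape-preserving cubic Hermite)
#'
#' Draws sorted uniform ordinates at equally spaced knots, pins the endpoints
#' at 0 and 1, and interpolates with a monotone (Fritsch-Carlson) piecewise
#' cubic Hermite scheme.  The result is a continuous non-decreasing map of
#' `[0, 1]` onto itself.
#'
#' @param n_knots number of knots (>= 3).
#' @return a function `f(u)` mapping `[0, 1] -> [0, 1]`.
#' @export
random_monotone_pchip <- function(n_knots = 5) {
  stopifnot(n_knots >= 3)
  x <- seq(0, 1, length.out = n_knots)
  y <- sort(runif(n_knots))
  y[1] <- 0; y[n_knots] <- 1
  f <- splinefun(x, y, method = "monoH.FC")
  function(u) pmin(pmax(f(u), 0), 1)
}

#' Distort the image histogram with a monotone mapping
#'
#' Applies `f` pixel-wise, emulating different lamp settings; pixel intensity
#' ordering is preserved for any monotone `f`.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param f monotone mapping, e.g. from [random_monotone_pchip()].
#' @return matrix of the same shape, values in `[0, 1]`.
#' @export
histogram_distort <- function(image, f) {
  matrix(pmin(pmax(f(as.vector(image)), 0), 1), nrow(image), ncol(image))
}

#' Modulate illumination along the chamber axis
#'
#' Multiplies row `r` of the image by `f(r / (H - 1))` (row axis = chamber
#' axis) and then maps the result linearly back to the original intensity
#' range, emulating illumination artefacts at the border between chip
#' regions under phase contrast.
#'
#' @param image numeric matrix.
#' @param f mapping on `[0, 1]`, e.g. from [random_monotone_pchip()] rescaled.
#' @return matrix with the same min/max as the input.
#' @export
illumination_distort <- function(image, f) {
  rng <- range(image)
  if (diff(rng) == 0) return(image)
  H <- nrow(image)
  g <- f((seq_len(H) - 1) / (H - 1))
  out <- image * g
  orng <- range(out)
  if (diff(orng) == 0) return(image)
  (out - orng[1]) / diff(orng) * diff(rng) + rng[1]
}

#' Smooth random elastic deformation
#'
#' One random displacement field, drawn on a coarse grid and densely
#' interpolated, is applied to every channel: intensity channels are sampled
#' bilinearly, binary/weight channels by nearest neighbour (so binary
#' channels stay binary).
#'
#' @param channels list of matrices (identical shape).
#' @param kinds character vector per channel: "intensity", "binary" or
#'   "weight".
#' @param grid_spacing coarse grid spacing in pixels.
#' @param sigma displacement standard deviation in pixels.
#' @return list of deformed matrices.
#' @export
elastic_deform <- function(channels, kinds, grid_spacing = 16, sigma = 1.5) {
  H <- nrow(channels[[1]]); W <- ncol(channels[[1]])
  stopifnot(length(kinds) == length(channels))
  if (sigma == 0) return(channels)
  gy <- unique(c(seq(1, H, by = grid_spacing), H))
  gx <- unique(c(seq(1, W, by = grid_spacing), W))
  dy_nodes <- matrix(rnorm(length(gy) * length(gx), 0, sigma),
                     length(gy), length(gx))
  dx_nodes <- matrix(rnorm(length(gy) * length(gx), 0, sigma),
                     length(gy), length(gx))
  dy <- bilinear_grid(dy_nodes, gy, gx, H, W)
  dx <- bilinear_grid(dx_nodes, gy, gx, H, W)
  ty <- matrix(seq_len(H), H, W) + dy
  tx <- matrix(seq_len(W), H, W, byrow = TRUE) + dx
  Map(function(ch, kind)
    warp_channel(ch, ty, tx, if (kind == "intensity") "bilinear" else "nearest"),
    channels, kinds)
}

# dense bilinear interpolation of values given on grid nodes (gy x gx)
bilinear_grid <- function(nodes, gy, gx, H, W) {
  iy <- findInterval(seq_len(H), gy, rightmost.closed = TRUE)
  ix <- findInterval(seq_len(W), gx, rightmost.closed = TRUE)
  iy <- pmin(iy, length(gy) - 1); ix <- pmin(ix, length(gx) - 1)
  fy <- (seq_len(H) - gy[iy]) / (gy[iy + 1] - gy[iy])
  fx <- (seq_len(W) - gx[ix]) / (gx[ix + 1] - gx[ix])
  A <- nodes[iy, ix, drop = FALSE]; B <- nodes[iy, ix + 1, drop = FALSE]
  C <- nodes[iy + 1, ix, drop = FALSE]; D <- nodes[iy + 1, ix + 1, drop = FALSE]
  Fy <- matrix(fy, H, W); Fx <- matrix(fx, H, W, byrow = TRUE)
  (1 - Fy) * ((1 - Fx) * A + Fx * B) + Fy * ((1 - Fx) * C + Fx * D)
}

#' Random geometric augmentation (shift, scale, rotation, flips)
#'
#' Samples a single transform from the configured ranges and applies it
#' identically to every channel (nearest neighbour for binary/weight
#' channels, bilinear otherwise); out-of-frame regions are filled by edge
#' replication.
#'
#' @inheritParams elastic_deform
#' @param config an [augment_config()].
#' @return list of transformed matrices.
#' @export
geometric_augment <- function(channels, kinds, config = augment_config()) {
  H <- nrow(channels[[1]]); W <- ncol(channels[[1]])
  shift <- runif(2, -config$shift_range, config$shift_range)
  scale <- 1 + runif(1, -config$scale_range, config$scale_range)
  theta <- runif(1, -config$rotation_range, config$rotation_range) * pi / 180
  fh <- config$flip_h && runif(1) < 0.5
  fv <- config$flip_v && runif(1) < 0.5
  apply_geometric(channels, kinds, shift, scale, theta, fh, fv)
}

# deterministic core of geometric_augment (also used by tests)
apply_geometric <- function(channels, kinds, shift = c(0, 0), scale = 1,
                            theta = 0, flip_h = FALSE, flip_v = FALSE) {
  H <- nrow(channels[[1]]); W <- ncol(channels[[1]])
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ty <- matrix(seq_len(H), H, W) - cy - shift[1]
  tx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx - shift[2]
  if (flip_v) ty <- -ty
  if (flip_h) tx <- -tx
  # inverse rotation + inverse scaling about the image centre
  sy <- ( cos(theta) * ty + sin(theta) * tx) / scale + cy
  sx <- (-sin(theta) * ty + cos(theta) * tx) / scale + cx
  Map(function(ch, kind)
    warp_channel(ch, sy, sx, if (kind == "intensity") "bilinear" else "nearest"),
    channels, kinds)
}

#' Apply one full augmentation draw to a sample's channels
#'
#' Order: geometric, then elastic, then intensity (the two monotone
#' remappings, applied with the same curves to every intensity channel).
#'
#' @inheritParams geometric_augment
#' @return list of augmented matrices.
#' @export
augment_sample <- function(channels, kinds, config = augment_config()) {
  out <- geometric_augment(channels, kinds, config)
  out <- elastic_deform(out, kinds, config$elastic_spacing,
                        config$elastic_sigma)
  intensity <- which(kinds == "intensity")
  if (length(intensity)) {
    if (config$histogram_distort_enabled) {
      f <- random_monotone_pchip(config$pchip_knots)
      for (i in intensity) out[[i]] <- histogram_distort(out[[i]], f)
    }
    if (config$illumination_distort_enabled) {
      g <- random_monotone_pchip(config$pchip_knots)
      lo <- runif(1, 0.5, 1)   # dimming band depth along the chamber axis
      fg <- function(u) lo + (1 - lo) * g(u)
      for (i in intensity) out[[i]] <- illumination_distort(out[[i]], fg)
    }
  }
  out
}
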
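#' Weight-map parameters
#'
#' Parameters of the border-emphasis weight map used when training the
#' segmentation network: `w(x) = wc(x) + w0 * exp(-(d1(x) + d2(x))^2 / (2 sigma^2))`
#' where `d1`, `d2` are the distances from a background pixel to its nearest
#' and second-nearest cell.  A 1-pixel cell contour is additionally set to
#' zero weight so the network is not forced to fit the exact outline drawn by
#' the curation step.
#'
#' @param w0 border emphasis amplitude (dimensionless, >= 0).
#' @param sigma border decay scale in pixels (> 0).
#' @return a `weight_params` list.
#' @export
weight_params <- function(w0 = 10, sigma = 5) {
  stopifnot(w0 >= 0, sigma > 0)
  structure(list(w0 = w0, sigma = sigma, contour_margin = 1L),
            class = "weight_params")
}

#' Class-balancing weight map
#'
#' Per-pixel weight `wc(x) = 0.5 / frequency(class(x))`, so that the mean
#' weight over the image is 1 whenever both classes are present and the loss
#' magnitude stays comparable across samples.  A single-class mask cannot be
#' balanced and yields a uniform map of ones (with a warning).
#'
#' @param mask binary matrix.
#' @return non-negative matrix, same shape as `mask`.
#' @export
class_balance_map <- function(mask) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  f <- mean(mask)
  if (f == 0 || f == 1) {
    warning("single-class mask: no class balancing possible")
    return(matrix(1, nrow(mask), ncol(mask)))
  }
  out <- matrix(0.5 / (1 - f), nrow(mask), ncol(mask))
  out[mask == 1] <- 0.5 / f
  out
}

#' Border-emphasis weight map
#'
#' Adds to the class-balance map a Gaussian emphasis on thin background gaps
#' separating two cells: `w0 * exp(-(d1 + d2)^2 / (2 sigma^2))` where `d1`
#' and `d2` are the Euclidean distances from each background pixel to the
#' nearest and second-nearest cell (8-connected components of `mask`).
#' With fewer than two cells the border term is zero everywhere (`d2` is
#' treated as infinite).
#'
#' @param mask binary matrix.
#' @param params a [weight_params()] object.
#' @return non-negative matrix `wc + border term`.
#' @export
border_weight_map <- function(mask, params = weight_params()) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  wc <- suppressWarnings(class_balance_map(mask))
  lab <- label_components(mask)
  ncell <- max(lab)
  if (ncell < 2) return(wc)
  H <- nrow(mask); W <- ncol(mask)
  # distance from every pixel to each component: distmap of the complement
  dists <- vapply(seq_len(ncell), function(k) {
    comp <- matrix(1, H, W)
    comp[lab == k] <- 0
    as.numeric(EBImage::distmap(comp, metric = "euclidean"))
  }, numeric(H * W))
  d12 <- t(apply(dists, 1, function(v) sort(v)[1:2]))
  border <- params$w0 * exp(-(d12[, 1] + d12[, 2])^2 / (2 * params$sigma^2))
  border[mask == 1] <- 0   # emphasis applies to background gap pixels
  wc + matrix(border, H, W)
}

#' Zero the loss weight on cell contour pixels
#'
#' Every cell pixel with at least one background pixel among its 8 neighbours
#' (the 1-pixel outer perimeter of each cell) gets weight 0; all other pixels
#' are unchanged.
#'
#' @param weights numeric matrix.
#' @param mask binary matrix, same shape.
#' @return `weights` with the contour set zeroed.
#' @export
zero_contour <- function(weights, mask) {
  stopifnot(all(dim(weights) == dim(mask)))
  weights[contour_pixels(mask)] <- 0
  weights
}

# logical matrix: cell pixels with a background pixel among their 8
# neighbours; pixels beyond the image border count as foreground so cells
# truncated by the crop edge keep their interior weight there
contour_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(1, H + 2, W + 2)          # outside treated as foreground
  pad[2:(H + 1), 2:(W + 1)] <- mask
  bg_adj <- matrix(FALSE, H, W)
  for (a in -1:1) for (b in -1:1) {
    if (a == 0 && b == 0) next
    bg_adj <- bg_adj | (pad[2:(H + 1) + a, 2:(W + 1) + b] == 0)
  }
  mask == 1 & bg_adj
}

#' Assemble a segmentation training sample
#'
#' Combines the min-max normalized image, the binary mask, and the weight map
#' `zero_contour(class-balance + border term)`.
#'
#' @param image numeric matrix.
#' @param mask binary matrix, same shape.
#' @param params a [weight_params()] object.
#' @return a `seg_sample` list with `image`, `mask`, `weights`.
#' @export
make_seg_sample <- function(image, mask, params = weight_params()) {
  stopifnot(all(dim(image) == dim(mask)))
  rng <- range(image)
  if (diff(rng) == 0) {
    warning("constant image normalized to all zeros")
    image <- matrix(0, nrow(image), ncol(image))
  } else {
    image <- (image - rng[1]) / diff(rng)
  }
  weights <- zero_contour(border_weight_map(mask, params), mask)
  structure(list(image = image, mask = mask, weights = weights),
            class = "seg_sample")
}

#' Build tracking training samples from ground truth
#'
#' For every cell and consecutive-frame pair in which the cell exists in the
#' earlier frame, builds a 4-input / 3-target sample: inputs are the previous
#' image, the seed-cell mask, the current image, and the current all-cells
#' mask; targets are the seed cell's region in the current frame, the
#' daughter region when a division occurred between the two frames, and
#' everything else.  A cell flushed out before the next frame yields empty
#' seed and daughter targets.
#'
#' @param lineage an `mm_lineage` (e.g. from [simulate_lineage()] ground
#'   truth or [assemble_lineage()]).
#' @param images list of transmitted-light matrices, one per frame.
#' @param masks list of labelled masks (labels = `cell_id`), one per frame.
#' @return list of `track_sample` objects (fields `inputs` H x W x 4 and
#'   `targets` H x W x 3).
#' @export
make_track_samples <- function(lineage, images, masks) {
  stopifnot(length(images) == length(masks))
  H <- nrow(masks[[1]]); W <- ncol(masks[[1]])
  out <- list()
  for (tr in lineage$tracks) {
    frames <- which(!vapply(tr$regions, is.null, logical(1)))
    for (t in frames) {
      if (t + 1 > length(masks)) next
      seed <- matrix(0, H, W); seed[tr$regions[[t]]] <- 1
      curr_all <- (masks[[t + 1]] > 0) * 1
      tgt_seed <- matrix(0, H, W)
      if (!is.null(tr$regions[[t + 1]]) && (t + 1) <= tr$last_frame)
        tgt_seed[tr$regions[[t + 1]]] <- 1
      tgt_dau <- matrix(0, H, W)
      dau_ids <- tr$daughter_ids[vapply(tr$daughter_ids, function(d)
        lineage$tracks[[as.character(d)]]$first_frame == t + 1, logical(1))]
      if (length(dau_ids) == 1) {
        dtr <- lineage$tracks[[as.character(dau_ids[[1]])]]
        tgt_dau[dtr$regions[[t + 1]]] <- 1
      }
      tgt_bg <- 1 - tgt_seed - tgt_dau
      inputs <- array(0, c(H, W, 4))
      inputs[, , 1] <- normalize01(images[[t]])
      inputs[, , 2] <- seed
      inputs[, , 3] <- normalize01(images[[t + 1]])
      inputs[, , 4] <- curr_all
      targets <- array(0, c(H, W, 3))
      targets[, , 1] <- tgt_seed
      targets[, , 2] <- tgt_dau
      targets[, , 3] <- tgt_bg
      out[[length(out) + 1]] <- structure(
        list(inputs = inputs, targets = targets,
             cell_id = tr$cell_id, frame = t),
        class = "track_sample")
    }
  }
  out
}

normalize01 <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) return(matrix(0, nrow(image), ncol(image)))
  (image - rng[1]) / diff(rng)
}

#' Write / read a segmentation sample directory (16-bit TIFF triplets)
#'
#' Samples round-trip bit-exactly at 16-bit quantization of the stored
#' image and weight scale.
#' @param sample a `seg_sample`.
#' @param dir directory; files `image.tif`, `mask.tif`, `weights.tif`.
#' @return `dir` (writer) / a `seg_sample` (reader).
#' @export
write_seg_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(sample$image, file.path(dir, "image.tif"), bits.per.sample = 16L)
  tiff::writeTIFF(sample$mask * 1.0, file.path(dir, "mask.tif"),
                  bits.per.sample = 16L)
  # weights exceed [0, 1]; store them on a 16-bit grid under a power-of-two
  # scale so that write -> read -> write round-trips bit-exactly
  wmax <- 2^ceiling(log2(max(sample$weights, 1)))
  tiff::writeTIFF(sample$weights / wmax, file.path(dir, "weights.tif"),
                  bits.per.sample = 16L)
  jsonlite::write_json(list(weight_scale = wmax), file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_seg_sample
#' @export
read_seg_sample <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  structure(list(
    image = tiff::readTIFF(file.path(dir, "image.tif")),
    mask = round(tiff::readTIFF(file.path(dir, "mask.tif"))),
    weights = round(tiff::readTIFF(file.path(dir, "weights.tif")) * 65535) /
      65535 * meta$weight_scale),
    class = "seg_sample")
}
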
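#' Network configuration
#'
#' Describes the encoder-decoder architecture: `levels` resolution levels
#' (two 3x3 same-padded convolutions + ReLU per level, 2x2 max-pooling on
#' the way down, learned 2x2 up-convolutions and skip concatenations on the
#' way up) and a final 1x1 convolution with sigmoid (segmentation, 1 output
#' channel) or per-pixel softmax (tracking, 3 output channels).  The spatial
#' input shape must be divisible by `2^(levels - 1)`.
#'
#' @param levels contraction depth (default 5).
#' @param base_filters feature maps at the first level (default 64; reduced
#'   configurations use 8).
#' @param in_channels 1 for segmentation, 4 for tracking.
#' @param out_channels 1 for segmentation, 3 for tracking.
#' @param final_activation `"sigmoid"` or `"softmax"`.
#' @param input_shape `c(H, W)` of the network input.
#' @return a `unet_config` list.
#' @export
unet_config <- function(levels = 5, base_filters = 64, in_channels = 1,
                        out_channels = 1,
                        final_activation = c("sigmoid", "softmax"),
                        input_shape = c(256, 32)) {
  final_activation <- match.arg(final_activation)
  stopifnot(levels >= 2, base_filters >= 1, in_channels >= 1,
            out_channels >= 1)
  div <- 2^(levels - 1)
  if (any(input_shape %% div != 0))
    stop("input_shape must be divisible by 2^(levels - 1)")
  structure(list(levels = as.integer(levels),
                 base_filters = as.integer(base_filters),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 final_activation = final_activation,
                 input_shape = as.integer(input_shape)),
            class = "unet_config")
}

#' Build a network with freshly initialized parameters
#'
#' Convolution weights are He-initialized (`sd = sqrt(2 / fan_in)`) from the
#' current R random stream, biases start at a small positive constant (which
#' keeps ReLUs initially active); two builds under the same seed are
#' identical.
#'
#' @param config a [unet_config()].
#' @return a `unet` object (`params` numeric vector + `config`).
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  layout <- unet_layout_cpp(config$levels, config$base_filters,
                            config$in_channels, config$out_channels)
  params <- unlist(lapply(layout, function(l)
    c(rnorm(l$wlen, sd = sqrt(2 / l$fan_in)), rep(0.01, l$blen))))
  structure(list(params = params, config = config, history = NULL),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<unet> %d levels, %d base filters, %d -> %d channels, %s head, %s params\n",
    cfg$levels, cfg$base_filters, cfg$in_channels, cfg$out_channels,
    cfg$final_activation, format(length(x$params), big.mark = ",")))
  invisible(x)
}

#' Run the network forward
#'
#' @param net a `unet`.
#' @param x input: `H x W` matrix (single channel) or `H x W x C` array.
#' @return `H x W x out_channels` probability array (sigmoid head: each value
#'   in (0, 1); softmax head: channels sum to 1 per pixel).
#' @export
predict_unet <- function(net, x) {
  cfg <- net$config
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  stopifnot(dim(x)[3] == cfg$in_channels,
            all(dim(x)[1:2] %% 2^(cfg$levels - 1) == 0))
  unet_forward_cpp(net$params, x, cfg$levels, cfg$base_filters,
                   cfg$in_channels, cfg$out_channels,
                   cfg$final_activation == "softmax")
}

#' Pixel-wise weighted binary cross-entropy
#'
#' `mean over pixels of w * (-t log p - (1 - t) log(1 - p))`, with
#' predictions clipped to `[1e-7, 1 - 1e-7]`.  This is the segmentation
#' training loss; the per-pixel weight map carries the border emphasis and
#' the zeroed contour margin.
#'
#' @param target binary matrix.
#' @param prediction matrix of probabilities.
#' @param weights non-negative matrix.
#' @return scalar loss.
#' @export
weighted_binary_crossentropy <- function(target, prediction, weights) {
  if (!all(dim(target) == dim(prediction)) ||
      !all(dim(target) == dim(weights)))
    stop("shape mismatch")
  eps <- 1e-7
  p <- pmin(pmax(prediction, eps), 1 - eps)
  mean(weights * (-target * log(p) - (1 - target) * log(1 - p)))
}

#' Categorical cross-entropy over one-hot pixel targets
#'
#' `mean over pixels of -log(prediction of the true channel)`; the tracking
#' training loss.  Targets must be one-hot per pixel and predictions on the
#' per-pixel probability simplex.
#'
#' @param targets `H x W x K` one-hot array.
#' @param predictions `H x W x K` simplex array.
#' @return scalar loss.
#' @export
categorical_crossentropy <- function(targets, predictions) {
  stopifnot(all(dim(targets) == dim(predictions)))
  sums <- apply(targets, c(1, 2), sum)
  if (!all(targets %in% c(0, 1)) || !all(sums == 1))
    stop("targets must be one-hot per pixel")
  eps <- 1e-7
  p <- pmin(pmax(predictions, eps), 1)
  -mean(apply(targets * log(p), c(1, 2), sum))
}

#' Training configuration
#'
#' Defaults follow the full-scale schedule: Adam with learning rate `1e-4`,
#' 400 epochs of 250 steps, batch size 10 for segmentation (5 for tracking).
#' Reduced desk-scale experiments shrink epochs/steps, not the optimizer.
#'
#' @param learning_rate Adam learning rate.
#' @param epochs,steps_per_epoch training schedule.
#' @param batch_size samples per optimizer step.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 400,
                         steps_per_epoch = 250, batch_size = 10) {
  stopifnot(learning_rate > 0, epochs >= 1, steps_per_epoch >= 1,
            batch_size >= 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 batch_size = as.integer(batch_size)),
            class = "train_config")
}

# one sample -> (x, target, wmap) arrays ready for the loss kernel
sample_tensors <- function(sample, cfg, augment = NULL) {
  if (inherits(sample, "seg_sample") ||
      (!is.null(sample$image) && !is.null(sample$mask))) {
    ch <- list(sample$image, sample$mask, sample$weights)
    kinds <- c("intensity", "binary", "weight")
    if (!is.null(augment)) ch <- augment_sample(ch, kinds, augment)
    list(x = array(ch[[1]], c(dim(ch[[1]]), 1)),
         target = array(ch[[2]], c(dim(ch[[2]]), 1)),
         wmap = ch[[3]])
  } else {
    ins <- sample$inputs; tgt <- sample$targets
    if (!is.null(augment)) {
      ch <- c(lapply(1:4, function(k) ins[, , k]),
              lapply(1:3, function(k) tgt[, , k]))
      kinds <- c("intensity", "binary", "intensity", "binary",
                 "binary", "binary", "binary")
      ch <- augment_sample(ch, kinds, augment)
      for (k in 1:4) ins[, , k] <- ch[[k]]
      for (k in 1:3) tgt[, , k] <- ch[[4 + k]]
    }
    list(x = ins, target = tgt, wmap = numeric(0))
  }
}

#' Train a network
#'
#' Runs `epochs x steps_per_epoch` Adam updates over an infinite stream of
#' (optionally augmented) samples with per-epoch reshuffling, keeps the
#' parameters of the best-epoch mean loss, and aborts on a non-finite loss.
#' Fully deterministic under a fixed R seed and single-threaded BLAS.
#'
#' @param net a `unet` from [build_unet()].
#' @param samples list of `seg_sample` or `track_sample` objects.
#' @param config a [train_config()].
#' @param augment optional [augment_config()]; applied on-the-fly.
#' @param verbose print per-epoch losses.
#' @return the trained `unet`, with a `history` data.frame (epoch, loss).
#' @export
train_unet <- function(net, samples, config = train_config(),
                       augment = NULL, verbose = FALSE) {
  cfg <- net$config
  softmax <- cfg$final_activation == "softmax"
  p <- net$params
  m <- numeric(length(p)); v <- numeric(length(p))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; it <- 0
  best_loss <- Inf; best_params <- p
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  n <- length(samples)
  for (ep in seq_len(config$epochs)) {
    need <- config$steps_per_epoch * config$batch_size
    idx <- integer(0)
    while (length(idx) < need) idx <- c(idx, sample.int(n))
    ep_loss <- 0
    for (st in seq_len(config$steps_per_epoch)) {
      take <- idx[((st - 1) * config$batch_size + 1):(st * config$batch_size)]
      g <- numeric(length(p)); loss <- 0
      for (i in take) {
        tn <- sample_tensors(samples[[i]], cfg, augment)
        lg <- unet_lossgrad_cpp(p, tn$x, tn$target, tn$wmap, cfg$levels,
                                cfg$base_filters, cfg$in_channels,
                                cfg$out_channels, softmax)
        g <- g + lg$grad; loss <- loss + lg$loss
      }
      g <- g / config$batch_size; loss <- loss / config$batch_size
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d step %d", ep, st))
      it <- it + 1
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      p <- p - config$learning_rate * (m / (1 - b1^it)) /
        (sqrt(v / (1 - b2^it)) + adam_eps)
      ep_loss <- ep_loss + loss
    }
    ep_loss <- ep_loss / config$steps_per_epoch
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss))
    if (ep_loss < best_loss) { best_loss <- ep_loss; best_params <- p }
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f%s", ep, ep_loss,
                      if (ep_loss <= best_loss) " *" else ""))
  }
  net$params <- best_params
  net$history <- history
  net
}

#' Segment a chamber image
#'
#' Runs the segmentation network, thresholds the probability map, and
#' removes connected components smaller than `min_area` pixels.
#'
#' @param net a trained segmentation `unet`.
#' @param image `H x W` matrix (min-max normalized internally).
#' @param threshold probability threshold (default 0.5).
#' @param min_area minimum component area in pixels (default 4).
#' @return binary matrix.
#' @export
segment_chamber <- function(net, image, threshold = 0.5, min_area = 4) {
  prob <- predict_unet(net, normalize01(image))[, , 1]
  mask <- (prob >= threshold) * 1
  lab <- label_components(mask)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    mask[lab %in% which(areas < min_area)] <- 0
  }
  mask
}

#' Track one seed cell into the current frame
#'
#' Feeds the four tracking inputs to the network, takes the per-pixel argmax
#' over the three output channels, and restricts the mother/daughter
#' candidate regions to the current segmentation foreground.  The regions
#' are disjoint by construction.
#'
#' @param net a trained tracking `unet`.
#' @param prev_image,curr_image transmitted-light matrices (normalized
#'   internally).
#' @param seed_mask binary matrix marking one cell in the previous frame.
#' @param curr_seg binary matrix of all segmented cells in the current frame.
#' @return list with logical matrices `mother` and `daughter`.
#' @export
track_cell <- function(net, prev_image, seed_mask, curr_image, curr_seg) {
  H <- nrow(seed_mask); W <- ncol(seed_mask)
  if (sum(seed_mask) == 0)
    return(list(mother = matrix(FALSE, H, W), daughter = matrix(FALSE, H, W)))
  x <- array(0, c(H, W, 4))
  x[, , 1] <- normalize01(prev_image)
  x[, , 2] <- (seed_mask != 0) * 1
  x[, , 3] <- normalize01(curr_image)
  x[, , 4] <- (curr_seg != 0) * 1
  out <- predict_unet(net, x)
  amax <- apply(out, c(1, 2), which.max)
  fg <- curr_seg != 0
  list(mother = amax == 1 & fg, daughter = amax == 2 & fg)
}

#' Save / load a network checkpoint (weights + JSON config sidecar)
#' @param net a `unet`.
#' @param path checkpoint path (an `.rds` file; a `.json` sidecar with the
#'   architecture is written next to it).
#' @return `path` (saver) / a `unet` (loader).
#' @export
save_unet <- function(net, path) {
  saveRDS(net, path)
  jsonlite::write_json(unclass(net$config),
                       paste0(sub("\\.rds$", "", path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "unet"))
  net
}
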
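#' Validate a run configuration
#'
#' The pipeline is configured by a nested list (typically read from YAML).
#' Unknown keys are rejected before any stage runs.
#'
#' @param config list or path to a YAML file.
#' @return the validated config list, invisibly on error-free validation.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("movie_dir", "template", "out_dir", "crop_shape", "max_shift",
             "seg_model", "track_model", "threshold", "min_area",
             "min_overlap", "dt", "seed", "truth_dir", "verbosity")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config
}

#' Run the full analysis pipeline on a chamber movie
#'
#' Stages: load (or receive) the chamber image stack, segment every frame,
#' track and assemble the lineage, and extract feature tables; when ground
#' truth is supplied the evaluation stage scores the result.  Every artifact
#' is stamped with the config and seed.
#'
#' @param images list of transmitted-light chamber matrices, or a directory
#'   containing `trans.tif` as written by [make_fixture_suite()].
#' @param seg_net,track_net trained networks (or paths to checkpoints saved
#'   with [save_unet()]).
#' @param out_dir output directory for artifacts (masks TIFF, lineage JSON,
#'   features CSV, eval JSON); `NULL` keeps everything in memory.
#' @param fluo optional list of fluorescence matrices.
#' @param truth optional `mm_groundtruth` for evaluation.
#' @param threshold,min_area passed to [segment_chamber()].
#' @param min_overlap passed to [resolve_assignments()].
#' @param dt frame interval in minutes.
#' @return list with `masks`, `lineage`, `features`, and (with truth)
#'   `seg_report` and `track_report`.
#' @export
run_pipeline <- function(images, seg_net, track_net, out_dir = NULL,
                         fluo = NULL, truth = NULL, threshold = 0.5,
                         min_area = 4, min_overlap = 0.5, dt = 5) {
  if (is.character(images)) {
    dir <- images
    images <- read_image_stack(file.path(dir, "trans.tif"))
    fp <- file.path(dir, "fluo.tif")
    if (is.null(fluo) && file.exists(fp)) fluo <- read_image_stack(fp)
  }
  if (is.character(seg_net)) seg_net <- load_unet(seg_net)
  if (is.character(track_net)) track_net <- load_unet(track_net)
  masks <- lapply(images, function(img)
    segment_chamber(seg_net, img, threshold = threshold,
                    min_area = min_area))
  lineage <- track_movie(track_net, images, masks,
                         min_overlap = min_overlap)
  features <- cell_time_series(lineage, fluo = fluo, dt = dt)
  out <- list(masks = masks, lineage = lineage, features = features)
  if (!is.null(truth)) {
    out$seg_report <- segmentation_errors(masks, truth$masks)
    out$track_report <- tracking_errors(lineage, truth$lineage,
                                        seg_report = out$seg_report)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_image_stack(lapply(masks, function(m) (m > 0) * 1),
                      file.path(out_dir, "masks.tif"))
    write_lineage_json(lineage, file.path(out_dir, "lineage.json"))
    write.csv(features, file.path(out_dir, "features.csv"),
              row.names = FALSE)
    if (!is.null(out$seg_report))
      write_eval_report(out$seg_report, file.path(out_dir, "seg_eval.json"))
  }
  out
}

#' Render a kymograph of a tracked chamber
#'
#' Lays the per-frame crops side by side, tinting each tracked cell by a
#' stable per-track shade and marking divisions, the standard way to
#' visualize growth and lineage in a chamber.
#'
#' @param images list of chamber matrices.
#' @param lineage an `mm_lineage`.
#' @param path optional PNG output path (requires the `png` package).
#' @return the kymograph as an `H x (W * n_frames) x 3` RGB array,
#'   invisibly when written to `path`.
#' @export
render_kymograph <- function(images, lineage, path = NULL) {
  H <- lineage$dim[1]; W <- lineage$dim[2]; n <- lineage$n_frames
  rgb_arr <- array(0, c(H, W * n, 3))
  ids <- vapply(lineage$tracks, `[[`, integer(1), "cell_id")
  hue <- (ids * 0.6180339887) %% 1            # golden-ratio hues
  for (t in seq_len(n)) {
    cols <- (t - 1) * W + seq_len(W)
    for (k in 1:3) rgb_arr[, cols, k] <- images[[t]]
    for (j in seq_along(lineage$tracks)) {
      tr <- lineage$tracks[[j]]
      if (is.null(tr$regions[[t]])) next
      col <- grDevices::hsv(hue[j], 0.6, 1)
      rgbv <- grDevices::col2rgb(col) / 255
      idx <- tr$regions[[t]]
      rr <- ((idx - 1) %% H) + 1
      cc <- ((idx - 1) %/% H) + 1 + (t - 1) * W
      for (k in 1:3)
        rgb_arr[cbind(rr, cc, k)] <-
          0.5 * rgb_arr[cbind(rr, cc, k)] + 0.5 * rgbv[k]
      # division mark: dark line at the boundary frame
      if (t %in% tr$division_frames)
        rgb_arr[cbind(min(rr), cc, 1)] <- 0
    }
  }
  if (!is.null(path)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to write PNG kymographs")
    png::writePNG(rgb_arr, path)
    return(invisible(rgb_arr))
  }
  rgb_arr
}

#' Reduced end-to-end training benchmark on synthetic movies
#'
#' Trains a reduced segmentation network and a reduced tracking network
#' (3 levels, 8 base filters, 128 x 32 chambers) on simulated movies, runs
#' the full pipeline on a held-out simulated movie, and scores it against
#' the simulator's ground truth.  This is the desk-scale stand-in for the
#' full GPU-scale training runs: it demonstrates that the architecture,
#' losses, augmentation and post-processing learn the task end to end.
#'
#' @param seed master seed; all simulation, initialization, and training
#'   randomness derives from it.
#' @param n_train_movies training movies (different seeds).
#' @param n_frames frames per movie.
#' @param seg_epochs,track_epochs training epochs (reduced schedule; the
#'   full-scale default is 400 x 250).
#' @param steps_per_epoch optimizer steps per epoch.
#' @param augment optional [augment_config()] applied during training.
#' @param verbose print progress.
#' @return list: `seg_rate`, `track_rate` (percent), `seg_report`,
#'   `track_report`, `pixel_error`, the trained nets and the held-out movie.
#' @export
synthetic_benchmark <- function(seed = 1, n_train_movies = 4, n_frames = 50,
                                seg_epochs = 12, track_epochs = 14,
                                steps_per_epoch = 40,
                                augment = augment_config(
                                  shift_range = 3, scale_range = 0.05,
                                  rotation_range = 2, elastic_sigma = 1),
                                verbose = FALSE) {
  params <- sim_params(chamber_height = 128, chamber_width = 32,
                       cell_width = 11, initial_length = 20,
                       division_length = 40, n_frames = n_frames)
  set.seed(seed)
  movie_seeds <- sample.int(1e6, n_train_movies + 1)
  train <- lapply(movie_seeds[-1], function(s) simulate_movie(params, s))
  heldout <- simulate_movie(params, movie_seeds[1])

  seg_samples <- list()
  for (gt in train)
    for (t in seq_len(gt$n_frames))
      seg_samples[[length(seg_samples) + 1]] <-
        make_seg_sample(gt$frames[[t]]$trans, (gt$masks[[t]] > 0) * 1)
  track_samples <- list()
  for (gt in train)
    track_samples <- c(track_samples,
                       make_track_samples(gt$lineage,
                                          lapply(gt$frames, `[[`, "trans"),
                                          gt$masks))
  # stratify the tracking stream: division samples are rare (~7%) and carry
  # the small daughter-channel signal, so the reduced schedule oversamples
  # them to about a quarter of the stream (the full-scale schedule sees
  # enough samples to learn divisions at their natural frequency)
  is_div <- vapply(track_samples, function(s) sum(s$targets[, , 2]) > 0,
                   logical(1))
  track_samples <- c(track_samples, rep(track_samples[is_div], 3))
  if (length(track_samples) > 400)
    track_samples <- track_samples[sample.int(length(track_samples), 400)]
  if (verbose)
    message(sprintf("training set: %d segmentation / %d tracking samples",
                    length(seg_samples), length(track_samples)))

  seg_net <- build_unet(unet_config(levels = 3, base_filters = 8,
                                    in_channels = 1, out_channels = 1,
                                    final_activation = "sigmoid",
                                    input_shape = c(128, 32)))
  seg_net <- train_unet(seg_net, seg_samples,
                        train_config(epochs = seg_epochs,
                                     steps_per_epoch = steps_per_epoch,
                                     batch_size = 10, learning_rate = 1e-3),
                        augment = augment, verbose = verbose)
  track_net <- build_unet(unet_config(levels = 3, base_filters = 8,
                                      in_channels = 4, out_channels = 3,
                                      final_activation = "softmax",
                                      input_shape = c(128, 32)))
  track_net <- train_unet(track_net, track_samples,
                          train_config(epochs = track_epochs,
                                       steps_per_epoch = steps_per_epoch,
                                       batch_size = 5, learning_rate = 1e-3),
                          augment = augment, verbose = verbose)

  res <- run_pipeline(lapply(heldout$frames, `[[`, "trans"),
                      seg_net, track_net, truth = heldout)
  seg_rate <- error_rate(sum(res$seg_report$counts),
                         res$seg_report$denominators["cells_evaluated"])
  track_rate <- if (res$track_report$events > 0)
    error_rate(res$track_report$errors, res$track_report$events) else NA_real_
  px <- mean(vapply(seq_len(heldout$n_frames), function(t)
    pixel_error(res$masks[[t]], heldout$masks[[t]] > 0), numeric(1)))
  list(seg_rate = unname(seg_rate), track_rate = unname(track_rate),
       pixel_error = px, seg_report = res$seg_report,
       track_report = res$track_report, seg_net = seg_net,
       track_net = track_net, heldout = heldout, result = res)
}
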
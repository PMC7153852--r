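test_that("loss closed forms: 2*ln2 single pixel and ln3 uniform simplex", {
  expect_equal(weighted_binary_crossentropy(matrix(1), matrix(0.5), matrix(2)),
               2 * log(2), tolerance = 1e-9)
  expect_equal(weighted_binary_crossentropy(matrix(1, 3, 3),
                                            matrix(0.5, 3, 3),
                                            matrix(0, 3, 3)), 0)
  tgt <- array(0, c(4, 4, 3)); tgt[, , 2] <- 1
  unif <- array(1 / 3, c(4, 4, 3))
  expect_equal(categorical_crossentropy(tgt, unif), log(3), tolerance = 1e-9)
  perfect <- tgt * (1 - 2e-7) + 1e-7
  expect_lt(categorical_crossentropy(tgt, perfect), 1e-5)
})

test_that("losses agree with scalar-loop oracles on random instances", {
  set.seed(20)
  for (rep in 1:25) {
    t <- matrix(rbinom(64, 1, 0.5), 8, 8)
    p <- matrix(runif(64), 8, 8)
    w <- matrix(runif(64, 0, 3), 8, 8)
    expect_equal(weighted_binary_crossentropy(t, p, w), oracle_wbce(t, p, w),
                 tolerance = 1e-9)
    lab <- matrix(sample(1:3, 64, TRUE), 8, 8)
    tg <- array(0, c(8, 8, 3))
    for (k in 1:3) tg[, , k] <- (lab == k) * 1
    pr <- array(runif(192), c(8, 8, 3))
    norm <- apply(pr, c(1, 2), sum)
    for (k in 1:3) pr[, , k] <- pr[, , k] / norm
    expect_equal(categorical_crossentropy(tg, pr), oracle_cce(tg, pr),
                 tolerance = 1e-9)
  }
  expect_error(weighted_binary_crossentropy(matrix(1), matrix(0.5, 2, 2),
                                            matrix(1)), "shape")
  bad <- array(0.5, c(2, 2, 3))
  expect_error(categorical_crossentropy(bad, bad), "one-hot")
})

test_that("network construction: shapes, activations, reproducibility, validation", {
  expect_error(unet_config(levels = 4, input_shape = c(30, 32)), "divisible")
  cfg <- unet_config(levels = 3, base_filters = 4, input_shape = c(32, 16))
  set.seed(30); n1 <- build_unet(cfg)
  set.seed(30); n2 <- build_unet(cfg)
  expect_identical(n1$params, n2$params)
  x <- matrix(runif(32 * 16), 32, 16)
  y <- predict_unet(n1, x)
  expect_equal(dim(y), c(32, 16, 1))
  expect_true(all(y > 0 & y < 1))
  tcfg <- unet_config(levels = 3, base_filters = 4, in_channels = 4,
                      out_channels = 3, final_activation = "softmax",
                      input_shape = c(32, 16))
  tn <- build_unet(tcfg)
  ty <- predict_unet(tn, array(runif(32 * 16 * 4), c(32, 16, 4)))
  expect_equal(apply(ty, c(1, 2), sum), matrix(1, 32, 16), tolerance = 1e-12)
  expect_true(all(ty >= 0))
})

test_that("default schedule matches the full-scale training constants", {
  tc <- train_config()
  expect_equal(tc$learning_rate, 1e-4)
  expect_equal(tc$epochs, 400L)
  expect_equal(tc$steps_per_epoch, 250L)
  expect_equal(tc$batch_size, 10L)
  expect_equal(tc$optimizer, "adam")
})

test_that("analytic gradients match central finite differences", {
  set.seed(33)
  lay <- mmtrack:::unet_layout_cpp(2L, 2L, 1L, 1L)
  p <- unlist(lapply(lay, function(l)
    c(rnorm(l$wlen, sd = sqrt(2 / l$fan_in)), rnorm(l$blen, sd = 0.1))))
  x <- array(runif(32), c(8, 4, 1))
  tg <- array(rbinom(32, 1, 0.5), c(8, 4, 1))
  w <- matrix(runif(32, 0.5, 2), 8, 4)
  g <- mmtrack:::unet_lossgrad_cpp(p, x, tg, w, 2L, 2L, 1L, 1L, FALSE)
  f <- function(pp) mmtrack:::unet_lossgrad_cpp(pp, x, tg, w, 2L, 2L,
                                                1L, 1L, FALSE)$loss
  idx <- sort(sample(length(p), 40))
  num <- vapply(idx, function(i) {
    e <- 1e-5; p1 <- p; p1[i] <- p[i] + e; p2 <- p; p2[i] <- p[i] - e
    (f(p1) - f(p2)) / (2 * e)
  }, numeric(1))
  expect_equal(g$grad[idx], num, tolerance = 1e-5)
})

test_that("the training-path loss equals the user-facing loss functions", {
  set.seed(34)
  cfg <- unet_config(levels = 2, base_filters = 2, input_shape = c(8, 8))
  net <- build_unet(cfg)
  x <- array(runif(64), c(8, 8, 1))
  tg <- array(rbinom(64, 1, 0.5), c(8, 8, 1))
  w <- matrix(runif(64, 0.5, 2), 8, 8)
  lg <- mmtrack:::unet_lossgrad_cpp(net$params, x, tg, w, 2L, 2L, 1L, 1L,
                                    FALSE)
  pred <- predict_unet(net, x)[, , 1]
  expect_equal(lg$loss, weighted_binary_crossentropy(tg[, , 1], pred, w),
               tolerance = 1e-9)
})

test_that("a tiny network trains: loss decreases, deterministically", {
  set.seed(35)
  samples <- lapply(1:20, function(i) {
    m <- matrix(0, 32, 16)
    r <- sample(4:20, 1)
    m[r:(r + 7), 6:11] <- 1
    img <- 0.75 - 0.5 * m + matrix(rnorm(32 * 16, 0, 0.03), 32, 16)
    make_seg_sample(img, m)
  })
  cfg <- unet_config(levels = 3, base_filters = 8, input_shape = c(32, 16))
  run <- function(seed) {
    set.seed(seed)
    net <- build_unet(cfg)
    train_unet(net, samples,
               train_config(epochs = 5, steps_per_epoch = 8,
                            batch_size = 4, learning_rate = 1e-3))
  }
  t1 <- run(77)
  expect_lt(tail(t1$history$loss, 1), t1$history$loss[1])
  t2 <- run(77)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$params, t2$params)
})

test_that("segmentation post-processing: thresholds are monotone and small components drop", {
  set.seed(36)
  cfg <- unet_config(levels = 2, base_filters = 2, input_shape = c(16, 8))
  net <- build_unet(cfg)
  img <- matrix(runif(16 * 8), 16, 8)
  m1 <- segment_chamber(net, img, threshold = 0.3, min_area = 1)
  m2 <- segment_chamber(net, img, threshold = 0.6, min_area = 1)
  expect_true(all(m2 <= m1))
  # an all-background probability map yields an empty mask
  pr <- predict_unet(net, img)
  if (all(pr < 1)) expect_true(TRUE)
  prob_empty <- segment_chamber(net, img, threshold = 1.01)
  expect_equal(sum(prob_empty), 0)
})

test_that("tracking outputs are disjoint, seed-gated, and restricted to the segmentation", {
  set.seed(37)
  cfg <- unet_config(levels = 2, base_filters = 2, in_channels = 4,
                     out_channels = 3, final_activation = "softmax",
                     input_shape = c(16, 8))
  net <- build_unet(cfg)
  img <- matrix(runif(128), 16, 8)
  seed_mask <- matrix(0, 16, 8); seed_mask[3:6, 3:6] <- 1
  seg <- matrix(0, 16, 8); seg[2:10, 2:7] <- 1
  out <- track_cell(net, img, seed_mask, img, seg)
  expect_equal(sum(out$mother & out$daughter), 0)
  expect_true(all(seg[out$mother] == 1))
  expect_true(all(seg[out$daughter] == 1))
  empty <- track_cell(net, img, matrix(0, 16, 8), img, seg)
  expect_equal(sum(empty$mother) + sum(empty$daughter), 0)
})

test_that("checkpoints round-trip through save/load", {
  set.seed(38)
  net <- build_unet(unet_config(levels = 2, base_filters = 2,
                                input_shape = c(8, 8)))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "seg.rds")
  save_unet(net, p)
  expect_true(file.exists(file.path(dir, "seg.json")))
  back <- load_unet(p)
  expect_identical(back$params, net$params)
})
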
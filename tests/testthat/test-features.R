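test_that("morphology: area is pixel count, length is chamber-axis extent", {
  H <- 20
  rect <- as.vector(outer(3:12, (2:4 - 1) * H, `+`))      # 10 x 3 rectangle
  m <- cell_morphology(rect, c(H, 6))
  expect_equal(m$area, 30)
  expect_equal(m$length, 10)
  expect_equal(cell_morphology(5, c(H, 6)), list(length = 1L, area = 1L))
  stair <- vapply(0:4, function(k) (1 + k) + k * H, numeric(1))  # diagonal
  ms <- cell_morphology(stair, c(H, 6))
  expect_equal(ms$area, 5)
  expect_equal(ms$length, 5)
  expect_error(cell_morphology(integer(0), c(H, 6)), "empty")
})

test_that("mean fluorescence equals the arithmetic mean over the region", {
  img <- matrix(7, 10, 10)
  expect_equal(mean_fluorescence(c(1, 5, 99), img), 7)
  img[1, 1] <- 10; img[2, 1] <- 30
  expect_equal(mean_fluorescence(c(1, 2), img), 20)
  set.seed(50)
  img <- matrix(runif(100), 10, 10)
  idx <- sample(100, 17)
  acc <- 0
  for (i in idx) acc <- acc + img[i]
  expect_equal(mean_fluorescence(idx, img), acc / 17, tolerance = 1e-12)
  expect_error(mean_fluorescence(integer(0), img), "empty")
})

test_that("growth rate recovers the exponential rate and skips division intervals", {
  lambda <- 0.021; dt <- 5
  L <- 20 * exp(lambda * dt * (0:9))
  r <- growth_rate(L, dt = dt)
  expect_equal(r, rep(lambda, 9), tolerance = 1e-12)
  expect_equal(growth_rate(rep(8, 5), dt = dt), rep(0, 4))
  r2 <- growth_rate(c(L[1:5], L[5] / 2 * exp(lambda * dt * (0:3))),
                    division_frames = 6, dt = dt)
  expect_equal(sum(is.na(r2)), 1)
  expect_true(is.na(r2[5]))
  expect_error(growth_rate(c(1, -1)), "non-positive")
})

test_that("cycle means split exactly at divisions and drop incomplete cycles", {
  sig <- c(1, 2, 3, 5, 7, 99)
  cm <- cycle_means(sig, frames = 1:6, division_frames = c(4, 6))
  expect_equal(cm, c(2, 6))
  expect_equal(cycle_means(rep(4, 6), 1:6, c(3, 5)), c(4, 4))
  # root cell: the first interval has no observed birth and is excluded
  cm2 <- cycle_means(sig, 1:6, c(4, 6), birth_observed = FALSE)
  expect_equal(cm2, 6)
  expect_length(cycle_means(sig, 1:6, integer(0)), 0)
})

test_that("generation correlation is 1 for identical ancestor/descendant signals", {
  # hand-built lineage: root divides at frames 5 and 9; daughters divide too
  mk_track <- function(id, mother, f0, f1, div, dau) list(
    cell_id = id, mother_id = mother, first_frame = f0, last_frame = f1,
    daughter_ids = dau, division_frames = div, exit_reason = "movie_end",
    regions = vector("list", 14))
  tracks <- list(
    `1` = mk_track(1L, NA_integer_, 1L, 14L, c(5L, 9L, 13L), c(2L, 3L, 4L)),
    `2` = mk_track(2L, 1L, 5L, 14L, c(9L, 13L), c(5L, 6L)),
    `3` = mk_track(3L, 1L, 9L, 14L, 13L, 7L),
    `5` = mk_track(5L, 2L, 9L, 14L, 13L, 8L),
    `4` = mk_track(4L, 1L, 13L, 14L, integer(0), integer(0)),
    `6` = mk_track(6L, 2L, 13L, 14L, integer(0), integer(0)),
    `7` = mk_track(7L, 3L, 13L, 14L, integer(0), integer(0)),
    `8` = mk_track(8L, 5L, 13L, 14L, integer(0), integer(0)))
  lin <- structure(list(tracks = tracks, dim = c(20L, 6L), n_frames = 14L),
                   class = "mm_lineage")
  # per-cycle constant signal, distinct across cycles, inherited identically
  series <- do.call(rbind, lapply(names(tracks), function(k) {
    tr <- tracks[[k]]
    data.frame(cell_id = tr$cell_id, frame = tr$first_frame:tr$last_frame,
               fluo = NA_real_)
  }))
  # each complete cycle holds the value of the cycle that spawned it
  assign_val <- function(cell, lo, hi, v) {
    series$fluo[series$cell_id == cell & series$frame >= lo &
                  series$frame < hi] <<- v
  }
  assign_val(1, 1, 5, 3); assign_val(1, 5, 9, 3); assign_val(1, 9, 13, 3)
  assign_val(2, 5, 9, 5); assign_val(2, 9, 13, 5)
  assign_val(3, 9, 13, 3); assign_val(5, 9, 13, 5)
  series <- series[!is.na(series$fluo), ]
  r <- generation_correlation(lin, series, gap = 1)
  expect_equal(as.numeric(r), 1)
  expect_gte(attr(r, "n_pairs"), 3)
})

test_that("generation correlation decays as phi^gap in simulated heritable expression", {
  # pairs pooled over 12 chambers: a single chamber shares one founder, so
  # per-chamber centering attenuates r and the cluster-level noise is large
  p <- sim_params(chamber_height = 128, chamber_width = 32, cell_width = 11,
                  initial_length = 20, division_length = 40,
                  phi = 0.8, n_frames = 150)
  gts <- lapply(1:12, function(s) simulate_lineage(p, seed = 42 + s))
  lins <- lapply(gts, `[[`, "lineage")
  sers <- lapply(gts, function(gt)
    data.frame(cell_id = gt$geometry$cell_id, frame = gt$geometry$frame,
               fluo = gt$geometry$fluor))
  r <- vapply(1:3, function(g)
    as.numeric(generation_correlation(lins, sers, gap = g)), numeric(1))
  expect_true(r[1] > r[2] && r[2] > r[3])
  for (g in 1:3) expect_lt(abs(r[g] - 0.8^g), 0.15)
  # independent signals give near-zero correlation
  set.seed(43)
  sers <- lapply(sers, function(s) { s$fluo <- rnorm(nrow(s)); s })
  r0 <- generation_correlation(lins, sers, gap = 1)
  expect_lt(abs(as.numeric(r0)), 0.15)
  expect_gte(attr(r0, "n_pairs"), 200)
})

test_that("pair order does not change the correlation", {
  gt <- simulate_lineage(sim_params(chamber_height = 128, chamber_width = 32,
                                    cell_width = 11, initial_length = 20,
                                    division_length = 40, n_frames = 120),
                         seed = 7)
  series <- data.frame(cell_id = gt$geometry$cell_id,
                       frame = gt$geometry$frame,
                       fluo = gt$geometry$fluor)
  r1 <- generation_correlation(gt$lineage, series, gap = 1)
  shuffled <- series[sample(nrow(series)), ]
  r2 <- generation_correlation(gt$lineage, shuffled, gap = 1)
  expect_equal(as.numeric(r1), as.numeric(r2), tolerance = 1e-12)
})

test_that("autocorrelation: normalization, white noise, AR(1) closed form", {
  set.seed(60)
  x <- rnorm(500)
  rho <- autocorrelation(x, max_lag = 20)
  expect_equal(unname(rho[1]), 1)
  # dual route: agrees with stats::acf
  ref <- as.numeric(stats::acf(x, lag.max = 20, plot = FALSE,
                               demean = TRUE)$acf)
  expect_equal(unname(rho), ref, tolerance = 1e-10)
  # white noise: negligible correlation at positive lags
  w <- rnorm(10000)
  rw <- autocorrelation(w, max_lag = 10)
  expect_true(all(abs(rw[-1]) < 0.05))
  # AR(1) with phi = 0.8
  phi <- 0.8
  n <- 10000
  ar <- numeric(n); ar[1] <- rnorm(1)
  for (i in 2:n) ar[i] <- phi * ar[i - 1] + rnorm(1)
  ra <- autocorrelation(ar, max_lag = 10)
  expect_true(all(abs(ra[as.character(1:10)] - phi^(1:10)) < 0.05))
  expect_error(autocorrelation(rep(3, 10)), "zero-variance")
  expect_error(autocorrelation(1), "short")
})

test_that("feature extraction on ground truth recovers simulated rates and intervals", {
  p <- sim_params(chamber_height = 128, chamber_width = 32, cell_width = 11,
                  initial_length = 20, division_length = 40,
                  growth_cv = 0, division_cv = 0, asymmetry_sd = 0,
                  growth_rate = log(2) / 25, n_frames = 26)
  gt <- simulate_lineage(p, seed = 1)
  # exact rate from the real-valued geometry of the mother's first cycle
  g1 <- gt$geometry[gt$geometry$cell_id == 1 & gt$geometry$frame <= 6, ]
  r <- growth_rate(g1$length, division_frames = 6, dt = 5)
  expect_equal(r[1:4], rep(log(2) / 25, 4), tolerance = 1e-9)
  # rasterized lengths track the real ones to discretization error
  series <- cell_time_series(gt$lineage, dt = 5)
  s1 <- series[series$cell_id == 1 & series$frame <= 5, ]
  expect_equal(s1$length, round(g1$length[1:5]), tolerance = 1.6)
  # the deterministic division interval is 5 frames (25 min doubling)
  divs <- gt$lineage$tracks[["1"]]$division_frames
  expect_true(all(diff(divs) == 5))
})
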
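# toy movie helpers: labelled 20 x 6 chamber frames from row ranges
toy_frame <- function(...) {
  cells <- list(...)
  m <- matrix(0L, 20, 6)
  for (k in seq_along(cells)) m[cells[[k]], 2:5] <- k
  m
}

test_that("attribution accepts at >= 90% of the predicted cell's surface", {
  gt <- matrix(0L, 20, 10); gt[1:10, 1:10] <- 1L       # 100 px
  pred91 <- matrix(0L, 20, 10)
  pred91[1:10, 1:10] <- 1L
  pred91[1:9, 1] <- 0L; pred91[11:19, 1] <- 1L         # 91 on gt, 9 off
  t91 <- match_to_groundtruth(pred91, gt)
  expect_equal(t91$gt_label, 1L)
  pred89 <- matrix(0L, 20, 10)
  pred89[1:10, 1:10] <- 1L
  pred89[10, 1:10] <- 0L; pred89[9, 1] <- 0L          # remove 11 on-gt px
  pred89[12, 1:10] <- 1L; pred89[13, 1] <- 1L         # add 11 off-gt px
  t89 <- match_to_groundtruth(pred89, gt)
  expect_true(is.na(t89$gt_label))
  # identical masks give a perfect bijection
  tid <- match_to_groundtruth(gt, gt)
  expect_equal(tid$gt_label, 1L)
  expect_length(attr(tid, "unmatched_gt"), 0)
  # a 50% overlap is rejected
  half <- matrix(0L, 20, 10); half[6:15, 1:10] <- 1L
  expect_true(is.na(match_to_groundtruth(half, gt)$gt_label))
})

test_that("perfect predictions yield a zero-error report (fixed point)", {
  gt <- tiny_movie(seed = 3, n_frames = 15)
  rep <- segmentation_errors(gt$masks, gt$masks)
  expect_equal(sum(rep$counts), 0L)
  expect_gte(rep$denominators[["cells_evaluated"]], 15)
})

test_that("a split one frame before the true division is waived", {
  gt_movie <- list(toy_frame(3:12), toy_frame(3:12), toy_frame(3:7, 9:13))
  pred_early <- list(toy_frame(3:12), toy_frame(3:7, 9:12),
                     toy_frame(3:7, 9:13))
  rep <- segmentation_errors(pred_early, gt_movie)
  expect_equal(unname(rep$counts["over_segmentation"]), 0L)
  expect_equal(sum(rep$counts), 0L)
  # without a division in the ground truth the same split is an error
  gt_static <- list(toy_frame(3:12), toy_frame(3:12), toy_frame(3:12))
  rep2 <- segmentation_errors(pred_early, gt_static)
  expect_equal(unname(rep2$counts["over_segmentation"]), 1L)
  # converse: prediction merges cells that just divided in the ground truth,
  # but itself divides next frame -> waived under-segmentation
  gt_early <- list(toy_frame(3:12), toy_frame(3:7, 9:12),
                   toy_frame(3:7, 9:13))
  pred_late <- list(toy_frame(3:12), toy_frame(3:12), toy_frame(3:7, 9:13))
  rep3 <- segmentation_errors(pred_late, gt_early)
  expect_equal(unname(rep3$counts["under_segmentation"]), 0L)
  pred_never <- list(toy_frame(3:12), toy_frame(3:12), toy_frame(3:12))
  rep4 <- segmentation_errors(pred_never, gt_early)
  expect_gte(unname(rep4$counts["under_segmentation"]), 1L)
})

test_that("spurious cells in the bottom 5-pixel margin are waived", {
  gt_movie <- list(toy_frame(3:10))
  spurious_margin <- toy_frame(3:10, 17:19)   # rows 17:19 within margin 16:20
  rep <- segmentation_errors(list(spurious_margin), gt_movie)
  expect_equal(sum(rep$counts), 0L)
  spurious_mid <- toy_frame(3:10, 12:14)      # same cell mid-chamber
  rep2 <- segmentation_errors(list(spurious_mid), gt_movie)
  expect_equal(unname(rep2$counts["false_positive"]), 1L)
  # missing gt cell in the margin is also waived
  gt_with_margin_cell <- list(toy_frame(3:10, 17:19))
  rep3 <- segmentation_errors(list(toy_frame(3:10)), gt_with_margin_cell)
  expect_equal(sum(rep3$counts), 0L)
  rep4 <- segmentation_errors(list(toy_frame(3:10)),
                              list(toy_frame(3:10, 12:14)))
  expect_equal(unname(rep4$counts["false_negative"]), 1L)
})

test_that("swapped sister assignments count as two tracking errors", {
  movie <- list(toy_frame(2:9), toy_frame(2:5, 7:10), toy_frame(2:5, 7:10))
  gt_assign <- list(
    data.frame(seed = "1", cell = c("1", "2"),
               type = c("mother", "daughter"), overlap = 16L),
    data.frame(seed = c("1", "2"), cell = c("1", "2"), type = "mother",
               overlap = 16L))
  pred_assign <- list(
    gt_assign[[1]],
    data.frame(seed = c("1", "2"), cell = c("2", "1"), type = "mother",
               overlap = 16L))
  gt_lin <- assemble_lineage(gt_assign, movie)
  pred_lin <- assemble_lineage(pred_assign, movie)
  res <- tracking_errors(pred_lin, gt_lin)
  expect_equal(res$errors, 2L)
  expect_equal(res$events, 3L)
  # identical lineages score zero errors
  res0 <- tracking_errors(gt_lin, gt_lin)
  expect_equal(res0$errors, 0L)
})

test_that("events tied to segmentation errors leave the denominator", {
  gt_movie <- list(toy_frame(3:10), toy_frame(3:10))
  pred_movie <- list(toy_frame(3:10), toy_frame(integer(0)))
  seg_rep <- segmentation_errors(pred_movie, gt_movie)
  expect_equal(unname(seg_rep$counts["false_negative"]), 1L)
  cont <- data.frame(seed = "1", cell = "1", type = "mother", overlap = 32L)
  gt_lin <- assemble_lineage(list(cont), gt_movie)
  pred_lin <- assemble_lineage(
    list(data.frame(seed = character(0), cell = character(0),
                    type = character(0), overlap = integer(0))),
    pred_movie)
  res <- tracking_errors(pred_lin, gt_lin, seg_report = seg_rep)
  expect_equal(res$errors, 0L)
  expect_equal(res$events, 0L)
  expect_equal(res$excluded, 1L)
})

test_that("error rates follow the printed convention and are scale-invariant", {
  expect_equal(error_rate(2, 3422), 0.06)
  expect_equal(error_rate(31, 3073), 1.01)
  expect_equal(error_rate(0, 100), 0)
  for (k in c(2, 5, 17))
    expect_equal(error_rate(3 * k, 1000 * k), error_rate(3, 1000))
  expect_error(error_rate(1, 0), "total")
})

test_that("pixel error counts disagreeing pixels over the chosen denominator", {
  a <- matrix(0, 10, 10)
  expect_equal(pixel_error(a, a), 0)
  b <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(pixel_error(b, 1 - b), 100)
  c1 <- matrix(0, 10, 10); c2 <- c1; c2[5, 5] <- 1
  expect_equal(pixel_error(c1, c2), 1)
  u1 <- matrix(0, 10, 10); u1[1:4, 1] <- 1
  u2 <- matrix(0, 10, 10); u2[3:6, 1] <- 1
  expect_equal(pixel_error(u1, u2, denominator = "union"), 100 * 4 / 6)
})

test_that("reports serialize with counts and a readable table", {
  gt <- list(toy_frame(3:10))
  rep <- segmentation_errors(list(toy_frame(3:10, 12:14)), gt)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$counts$false_positive, 1)
  expect_true(file.exists(sub("\\.json$", ".txt", path)))
})
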
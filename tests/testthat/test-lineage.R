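mk_scores <- function(mother, daughter = NULL, areas = NULL) {
  ns <- nrow(mother); nc <- ncol(mother)
  if (is.null(daughter)) daughter <- matrix(0L, ns, nc)
  if (is.null(areas)) areas <- rep(1L, nc)   # permissive eligibility
  structure(list(mother = mother, daughter = daughter,
                 cell_areas = as.integer(areas),
                 seed_ids = as.character(seq_len(ns)),
                 cell_ids = as.character(seq_len(nc))),
            class = "mm_scores")
}

test_that("attribute_scores counts overlap pixels exactly", {
  lab <- matrix(0L, 10, 10)
  lab[2:6, 2:7] <- 1L        # cell 1, 30 px
  lab[8:9, 2:6] <- 2L        # cell 2, 10 px
  mo <- matrix(FALSE, 10, 10); mo[2:6, 2:7] <- TRUE
  da <- matrix(FALSE, 10, 10)
  sc <- attribute_scores(list(s1 = list(mother = mo, daughter = da)), lab)
  expect_equal(unname(sc$mother["s1", ]), c(30L, 0L))
  expect_equal(sc$cell_areas, c(30L, 10L))
  # constructed partial overlaps: 12 px on cell 1, 5 px on cell 2
  mo2 <- matrix(FALSE, 10, 10); mo2[3:6, 2:4] <- TRUE
  da2 <- matrix(FALSE, 10, 10); da2[8, 2:6] <- TRUE
  sc2 <- attribute_scores(list(s1 = list(mother = mo2, daughter = da2)), lab)
  expect_equal(unname(sc2$mother["s1", ]), c(12L, 0L))
  expect_equal(unname(sc2$daughter["s1", ]), c(0L, 5L))
  # empty tracking output: all-zero row
  sc3 <- attribute_scores(list(s1 = list(mother = da, daughter = da)), lab)
  expect_true(all(sc3$mother == 0) && all(sc3$daughter == 0))
})

test_that("diagonal-dominant matrices resolve to pure continuation", {
  sc <- mk_scores(diag(c(30L, 40L, 25L)), areas = c(30, 40, 25))
  a <- resolve_assignments(sc)
  expect_equal(nrow(a), 3)
  expect_true(all(a$type == "mother"))
  expect_equal(a$seed, a$cell)
  expect_length(attr(a, "roots"), 0)
})

test_that("a division resolves into continuation plus daughter link", {
  mo <- matrix(c(28L, 0L), 1, 2)
  da <- matrix(c(0L, 22L), 1, 2)
  a <- resolve_assignments(mk_scores(mo, da, areas = c(28, 22)))
  expect_equal(nrow(a), 2)
  expect_setequal(a$type, c("mother", "daughter"))
  expect_equal(a$cell[a$type == "mother"], "1")
  expect_equal(a$cell[a$type == "daughter"], "2")
})

test_that("exactly tied top scores make the contested cell a new root", {
  mo <- rbind(c(10L, 9L), c(10L, 0L))     # both seeds hit cell 1 with 10
  a <- resolve_assignments(mk_scores(mo, areas = c(10, 9)))
  expect_true("1" %in% attr(a, "roots"))
  # seed 1 falls through to its next-best option
  expect_equal(a$cell[a$seed == "1"], "2")
})

test_that("sub-threshold overlap leaves the new cell unlinked", {
  mo <- matrix(10L, 1, 1)
  a <- resolve_assignments(mk_scores(mo, areas = 30))   # 10 < 0.5 * 30
  expect_equal(nrow(a), 0)
  expect_equal(attr(a, "roots"), "1")
})

test_that("resolution is maximum-total-overlap: exhaustive enumeration agreement", {
  set.seed(44)
  for (rep in 1:40) {
    ns <- sample(1:4, 1); nc <- sample(1:4, 1)
    mo <- matrix(sample(0:9, ns * nc, TRUE), ns, nc)
    da <- matrix(sample(0:9, ns * nc, TRUE) *
                   rbinom(ns * nc, 1, 0.4), ns, nc)
    areas <- rep(2L, nc)    # eligibility mostly permissive, some ties likely
    a <- resolve_assignments(mk_scores(mo, da, areas))
    oracle <- oracle_resolve(mo, da, areas)
    expect_equal(attr(a, "total"), max(oracle$total, 0))
    # the returned links are one of the oracle's optimal valid sets
    if (nrow(a)) {
      key <- function(set) paste(sort(apply(set, 1, paste, collapse = ":")),
                                 collapse = ";")
      mine <- key(cbind(as.integer(a$seed), as.integer(a$cell),
                        ifelse(a$type == "mother", 1L, 2L), a$overlap))
      oracle_keys <- vapply(oracle$sets, function(s)
        key(do.call(rbind, s)), character(1))
      expect_true(mine %in% oracle_keys)
    }
  }
})

test_that("a 3-frame movie with one division assembles the expected tree", {
  H <- 20; W <- 6
  mk <- function(cells) {
    m <- matrix(0L, H, W)
    for (k in seq_along(cells)) m[cells[[k]], 2:5] <- k
    m
  }
  movie <- list(mk(list(3:10)), mk(list(3:12)), mk(list(3:7, 9:13)))
  a12 <- data.frame(seed = "1", cell = "1", type = "mother", overlap = 40L)
  a23 <- data.frame(seed = c("1", "1"), cell = c("1", "2"),
                    type = c("mother", "daughter"), overlap = c(20L, 20L))
  lin <- assemble_lineage(list(a12, a23), movie)
  expect_length(lin$tracks, 2)
  expect_equal(lin$tracks[["2"]]$mother_id, 1L)
  expect_equal(lin$tracks[["2"]]$first_frame, 3L)
  expect_equal(lin$tracks[["1"]]$division_frames, 3L)
  expect_equal(lin$tracks[["1"]]$daughter_ids, 2L)
  expect_equal(lin$tracks[["1"]]$exit_reason, "movie_end")
  # a movie with no divisions keeps one track per first-frame cell
  movie2 <- list(mk(list(3:10)), mk(list(4:11)))
  lin2 <- assemble_lineage(list(a12), movie2)
  expect_length(lin2$tracks, 1)
  # referencing a nonexistent region is an integrity error
  bad <- data.frame(seed = "1", cell = "7", type = "mother", overlap = 5L)
  expect_error(assemble_lineage(list(bad), movie2), "nonexistent")
})

test_that("ground-truth bypass reproduces the simulated lineage exactly", {
  gt <- tiny_movie(seed = 5, n_frames = 30)
  assigns <- gt_bypass_assignments(gt)
  lin <- assemble_lineage(assigns, gt$masks)
  expect_length(lin$tracks, length(gt$lineage$tracks))
  res <- tracking_errors(lin, gt$lineage)
  expect_equal(res$errors, 0L)
  expect_equal(res$excluded, 0L)
  expect_gt(res$events, 50)
  # conservation: per frame, track regions partition the foreground
  lm <- lineage_masks(lin)
  for (t in seq_len(gt$n_frames)) {
    expect_equal(sum(lm[[t]] > 0), sum(gt$masks[[t]] > 0))
    expect_true(all((lm[[t]] > 0) == (gt$masks[[t]] > 0)))
  }
})

test_that("lineage JSON round-trips regions, links and divisions", {
  gt <- tiny_movie(seed = 9, n_frames = 15)
  path <- withr::local_tempfile(fileext = ".json")
  write_lineage_json(gt$lineage, path)
  back <- read_lineage_json(path)
  expect_equal(length(back$tracks), length(gt$lineage$tracks))
  for (key in names(gt$lineage$tracks)) {
    a <- gt$lineage$tracks[[key]]; b <- back$tracks[[key]]
    expect_equal(b$mother_id, a$mother_id)
    expect_equal(b$division_frames, a$division_frames)
    for (t in seq_len(gt$n_frames)) {
      if (is.null(a$regions[[t]])) expect_null(b$regions[[t]])
      else expect_equal(sort(b$regions[[t]]),
                        sort(as.integer(a$regions[[t]])),
                        ignore_attr = TRUE)
    }
  }
})
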
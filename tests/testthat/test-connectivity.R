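test_that("pearsonMatrix reproduces perfect and anti-correlation", {
  set.seed(10)
  x <- rnorm(50)
  ts <- cbind(a = x, b = 2 * x + 1, c = -x, d = rnorm(50))
  m <- pearsonMatrix(ts)
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(m["a", "b"], 1)       # identical up to positive affine map
  expect_equal(m["a", "c"], -1)      # sign-flipped copy
  expect_equal(m, t(m))
})

test_that("pearsonMatrix is invariant to positive affine rescaling per column", {
  set.seed(11)
  ts <- matrix(rnorm(40 * 6), 40, 6)
  slopes <- runif(6, 0.5, 4)
  shifts <- rnorm(6, sd = 10)
  scaled <- sweep(sweep(ts, 2, slopes, "*"), 2, shifts, "+")
  expect_equal(pearsonMatrix(scaled), pearsonMatrix(ts), tolerance = 1e-12)
})

test_that("zero-variance region raises an error naming the region", {
  ts <- cbind(A1 = rnorm(20), FLAT = rep(5, 20), A3 = rnorm(20))
  expect_error(pearsonMatrix(ts), "FLAT")
})

test_that("a 90-region series yields 4005 connectivity features", {
  set.seed(12)
  ts <- roiTimeSeries(matrix(rnorm(120 * 90), 120, 90))
  v <- vectorizeUpper(pearsonMatrix(ts))
  expect_length(v, 4005L)
  expect_true(all(abs(v) <= 1 + 1e-12))
  expect_equal(names(v)[1], "PreCG.L__PreCG.R")
})

test_that("vectorizeUpper follows the row-major pair order", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.12
  m[1, 3] <- m[3, 1] <- 0.13
  m[2, 3] <- m[3, 2] <- 0.23
  expect_equal(unname(vectorizeUpper(m)), c(0.12, 0.13, 0.23))
  bad <- m; bad[1, 2] <- 0.5
  expect_error(vectorizeUpper(bad), "asymmetric")
})

test_that("pair index mapping matches enumeration and is a bijection", {
  # combn enumerates pairs in exactly the declared row-major order
  for (R in c(3L, 4L, 7L, 20L, 90L, 120L)) {
    P <- R * (R - 1L) / 2L
    expected <- t(combn(R, 2L))
    got <- pairOfIndex(seq_len(P), R)
    expect_equal(unname(got), unname(expected))
    expect_equal(indexOfPair(got[, 1], got[, 2], R), seq_len(P))
  }
  # published landmarks (1-based): first, 89th and last of 4005
  expect_equal(unname(pairOfIndex(1, 90)[1, ]), c(1L, 2L))
  expect_equal(unname(pairOfIndex(89, 90)[1, ]), c(1L, 90L))
  expect_equal(unname(pairOfIndex(4005, 90)[1, ]), c(89L, 90L))
  expect_error(pairOfIndex(4006, 90), "out of range")
  expect_error(indexOfPair(5, 5, 90), "i < j")
})

test_that("head-motion QC excludes strictly beyond the 2mm / 2deg limits", {
  expect_false(motionQC(2.5, 0.1))   # translation exceeded
  expect_false(motionQC(0.1, 2.5))   # rotation exceeded
  expect_true(motionQC(0, 0))
  expect_true(motionQC(2.0, 2.0))    # exactly at the limits: kept
  expect_equal(motionQC(c(1, 3), c(1, 0)), c(TRUE, FALSE))
  expect_error(motionQC(-1, 0), "non-negative")
})

test_that("the packaged AAL-90 table is complete and hemisphere-alternating", {
  aal <- aal90Regions()
  expect_equal(nrow(aal), 90L)
  expect_equal(aal$index, 1:90)
  expect_equal(aal$hemisphere, rep(c("L", "R"), 45))
  expect_true(all(c("ORBinf.L", "SFGdor.L", "PreCG.L", "ACG.R", "CAL.L")
                  %in% aal$abbreviation))
  expect_false(anyDuplicated(aal$abbreviation) > 0)
})

test_that("ROI time series round-trip through CSV", {
  dir <- withr::local_tempdir()
  ts <- roiTimeSeries(matrix(rnorm(30 * 5), 30, 5), subject_id = "S1",
                      region_labels = paste0("reg", 1:5))
  write.csv(as.data.frame(ts$data), file.path(dir, "S1.csv"),
            row.names = FALSE)
  back <- readRoiTimeSeries(file.path(dir, "S1.csv"))
  expect_equal(back$data, ts$data)
  expect_equal(back$subject_id, "S1")
})
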
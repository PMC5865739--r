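test_that("null spec yields background-level connectivity and empty truth", {
  spec <- syntheticSpec(n_group_a = 4L, n_group_b = 4L, n_regions = 10L,
                        n_timepoints = 200L, planted_pairs = NULL,
                        baseline_corr = 0, noise_sd = 0, seed = 7L)
  coh <- generateCohort(spec)
  expect_length(coh$truth, 0L)
  expect_false(coh$repaired)
  ds <- connectivityFeatures(coh)
  # entries scatter around 0 at the 1/sqrt(T) scale
  expect_lt(abs(mean(ds$features)), 0.05)
  expect_lt(max(abs(ds$features)), 0.5)
})

test_that("planted correlations are recovered at large T (law of large numbers)", {
  spec <- syntheticSpec(n_group_a = 2L, n_group_b = 2L, n_regions = 3L,
                        n_timepoints = 10000L,
                        planted_pairs = data.frame(i = 1L, j = 2L,
                                                   corr_a = 0.9,
                                                   corr_b = -0.9),
                        baseline_corr = 0.1, noise_sd = 0, seed = 8L)
  coh <- generateCohort(spec)
  corrs <- vapply(coh$subjects,
                  function(s) pearsonMatrix(s)[1, 2], numeric(1))
  expect_equal(mean(corrs[coh$labels == "A"]), 0.9, tolerance = 0.05)
  expect_equal(mean(corrs[coh$labels == "B"]), -0.9, tolerance = 0.05)
  expect_equal(coh$truth, indexOfPair(1L, 2L, 3L))
})

test_that("identical spec and seed reproduce the cohort exactly", {
  spec <- smallSpec(seed = 9L)
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  expect_identical(c1$labels, c2$labels)
  expect_identical(lapply(c1$subjects, `[[`, "data"),
                   lapply(c2$subjects, `[[`, "data"))
  # and a different seed does not
  c3 <- generateCohort(smallSpec(seed = 10L))
  expect_false(identical(c1$subjects[[1]]$data, c3$subjects[[1]]$data))
})

test_that("unplanted pairs share the same target correlation in both groups", {
  spec <- smallSpec()
  Sa <- rsvmcluster:::groupTargetMatrix(spec, "a")
  Sb <- rsvmcluster:::groupTargetMatrix(spec, "b")
  planted <- cbind(spec$planted_pairs$i, spec$planted_pairs$j)
  mask <- upper.tri(Sa)
  mask[planted] <- FALSE
  expect_equal(Sa[mask], Sb[mask])
  expect_true(all(Sa[mask] == spec$baseline_corr))
})

test_that("non-PSD targets are repaired by eigenvalue clipping and recorded", {
  # a correlation triangle that violates PSD: r12 = r13 = 0.9, r23 = -0.9
  pp <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                   corr_a = c(0.9, 0.9, -0.9), corr_b = 0)
  expect_error(
    generateCohort(syntheticSpec(n_group_a = 2L, n_group_b = 2L,
                                 n_regions = 3L, n_timepoints = 50L,
                                 planted_pairs = pp, baseline_corr = 0,
                                 noise_sd = 0, seed = 1L)),
    "not positive semi-definite")
  # a mild violation is repaired silently but flagged
  pp2 <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                    corr_a = c(0.73, 0.73, 0), corr_b = 0)
  coh <- generateCohort(syntheticSpec(n_group_a = 2L, n_group_b = 2L,
                                      n_regions = 3L, n_timepoints = 50L,
                                      planted_pairs = pp2, baseline_corr = 0,
                                      noise_sd = 0, seed = 1L))
  expect_true(coh$repaired)
})

test_that("spec validation rejects malformed planted pairs and sizes", {
  expect_error(syntheticSpec(n_group_a = 1L), "at least 2")
  expect_error(syntheticSpec(n_timepoints = 5L), "at least 10")
  expect_error(
    syntheticSpec(planted_pairs = data.frame(i = 5L, j = 3L,
                                             corr_a = 0.5, corr_b = 0)),
    "i < j")
  expect_error(
    syntheticSpec(planted_pairs = data.frame(i = 1L, j = 2L,
                                             corr_a = 1.5, corr_b = 0)),
    "\\[-1, 1\\]")
})

test_that("cohorts round-trip through the CSV manifest format", {
  dir <- withr::local_tempdir()
  coh <- generateCohort(smallSpec())
  writeCohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  back <- readCohort(dir)
  expect_equal(as.character(back$labels), as.character(coh$labels))
  expect_equal(back$truth, coh$truth)
  expect_equal(back$subjects[[5]]$data, coh$subjects[[5]]$data,
               tolerance = 1e-12)
})
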
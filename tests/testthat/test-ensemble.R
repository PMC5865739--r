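test_that("splitDataset partitions with the requested sizes, reproducibly", {
  ds <- smallDataset()
  sp <- splitDataset(ds, sizes = c(16, 2, 6), seed = 21)
  expect_length(sp$train_idx, 16L)
  expect_length(sp$test_idx, 2L)
  expect_length(sp$validation_idx, 6L)
  all_idx <- c(sp$train_idx, sp$test_idx, sp$validation_idx)
  expect_equal(sort(all_idx), seq_len(24))        # disjoint, exhaustive
  expect_identical(splitDataset(ds, c(16, 2, 6), seed = 21), sp)
  # both classes present where required
  expect_equal(nlevels(droplevels(ds$labels[sp$train_idx])), 2L)
  expect_equal(nlevels(droplevels(ds$labels[sp$validation_idx])), 2L)
  # degenerate all-train split
  sp0 <- splitDataset(ds, sizes = c(24, 0, 0), seed = 1)
  expect_length(sp0$train_idx, 24L)
  expect_length(sp0$test_idx, 0L)
  expect_error(splitDataset(ds, sizes = c(10, 2, 6), seed = 1), "sum")
})

test_that("buildCluster is reproducible and honours n, d, k", {
  ds <- smallDataset()
  sp <- smallSplit(ds)
  cl <- buildCluster(ds, sp, n = 16, d = 14, k = 10, seed = 31)
  expect_s3_class(cl, "randomSvmCluster")
  expect_length(cl$members, 10L)
  for (m in cl$members) {
    expect_length(m$sample_idx, 16L)
    expect_true(all(m$sample_idx %in% sp$train_idx))
    expect_length(m$feature_idx, 14L)
    expect_false(is.unsorted(m$feature_idx, strictly = TRUE))  # distinct, sorted
  }
  cl2 <- buildCluster(ds, sp, n = 16, d = 14, k = 10, seed = 31)
  expect_identical(lapply(cl$members, `[[`, "sample_idx"),
                   lapply(cl2$members, `[[`, "sample_idx"))
  expect_identical(lapply(cl$members, `[[`, "feature_idx"),
                   lapply(cl2$members, `[[`, "feature_idx"))
  expect_error(buildCluster(ds, sp, d = 500, k = 2), "exceeds the feature pool")
  expect_error(buildCluster(ds, sp, n = 20, k = 2, replace = FALSE),
               "exceeds training-set size")
})

test_that("majority vote equals the brute-force mode of member votes", {
  ds <- smallDataset()
  sp <- smallSplit(ds)
  for (k in c(3L, 8L, 25L)) {           # odd and even ensembles
    cl <- buildCluster(ds, sp, n = 16, d = 10, k = k, seed = 40 + k)
    newdata <- ds$features
    mv <- rsvmcluster:::memberVotes(cl, newdata)
    pred <- predict(cl, newdata, type = "votes")
    pos <- cl$positive_class
    neg <- setdiff(cl$levels, pos)
    for (r in seq_len(nrow(newdata))) {
      counts <- table(factor(mv$votes[r, ], levels = cl$levels))
      expect_equal(unname(pred$votes[r, pos]), unname(counts[[pos]]))
      if (counts[[pos]] != counts[[neg]]) {
        # strict majority: prediction is the mode
        expect_equal(as.character(pred$class[r]),
                     names(counts)[which.max(counts)])
      } else {
        # tie: documented rule, sign of summed decision values
        expected <- if (sum(mv$decision_values[r, ]) > 0) pos else neg
        expect_equal(as.character(pred$class[r]), expected)
      }
    }
  }
})

test_that("a k = 1 cluster reproduces its single member's predictions", {
  ds <- smallDataset()
  sp <- smallSplit(ds)
  cl <- buildCluster(ds, sp, n = 16, d = 14, k = 1, seed = 50,
                     replace = FALSE)
  m <- cl$members[[1]]
  own <- predict(m$model, ds$features[, m$feature_idx, drop = FALSE])
  expect_equal(as.character(predict(cl, ds$features)), as.character(own))
})

test_that("accuracies live on the 1/|eval| grid and match counting", {
  ds <- smallDataset()
  sp <- smallSplit(ds)
  cl <- buildCluster(ds, sp, n = 16, d = 14, k = 20, seed = 60)
  acc <- memberAccuracies(cl, ds, sp$validation_idx)
  expect_length(acc, 20L)
  expect_true(all(acc >= 0 & acc <= 1))
  n_eval <- length(sp$validation_idx)
  expect_true(all(abs(acc * n_eval - round(acc * n_eval)) < 1e-9))
  ca <- clusterAccuracy(cl, ds, sp$validation_idx)
  pred <- predict(cl, ds$features[sp$validation_idx, , drop = FALSE])
  expect_equal(ca, mean(as.character(pred) ==
                        as.character(ds$labels[sp$validation_idx])))
  expect_error(clusterAccuracy(cl, ds, integer()), "non-empty")
  expect_error(memberAccuracies(cl, ds, integer()), "non-empty")
})

test_that("the validation-accuracy formula gives 94.44% for 17 of 18", {
  expect_equal(round(100 * 17 / 18, 2), 94.44)
})

test_that("ensemble predictions are fully deterministic under a fixed seed", {
  ds <- smallDataset()
  sp <- smallSplit(ds)
  run <- function() {
    cl <- buildCluster(ds, sp, n = 16, d = 14, k = 15, seed = 70)
    list(pred = predict(cl, ds$features),
         acc = clusterAccuracy(cl, ds, sp$validation_idx),
         macc = memberAccuracies(cl, ds, sp$validation_idx))
  }
  expect_identical(run(), run())
})

test_that("sweepK traces one accuracy per ensemble size", {
  ds <- smallDataset()
  sp <- smallSplit(ds)
  curve <- sweepK(ds, sp, n = 16, d = 14, k_values = c(5, 15), seed = 80)
  expect_equal(curve$k, c(5L, 15L))
  expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 1))
  expect_error(sweepK(ds, sp, k_values = c(10, 5)), "ascending")
  # single k value equals a direct clusterAccuracy with the derived seed
  single <- sweepK(ds, sp, n = 16, d = 14, k_values = 10L, seed = 81)
  seed1 <- rsvmcluster:::deriveSeeds(81, 1L)
  cl <- buildCluster(ds, sp, n = 16, d = 14, k = 10, seed = seed1)
  expect_equal(single$accuracy, clusterAccuracy(cl, ds, sp$validation_idx))
})

test_that("tuneParams returns a grid point maximizing test-set accuracy", {
  ds <- smallDataset()
  sp <- smallSplit(ds)
  single <- tuneParams(ds, sp, gamma_grid = 3, cost_grid = Inf,
                       n = 16, d = 14, k = 10, seed = 90)
  expect_equal(single$gamma, 3)
  expect_equal(single$cost, Inf)
  tuned <- tuneParams(ds, sp, gamma_grid = c(0.5, 3), cost_grid = c(1, Inf),
                      n = 16, d = 14, k = 10, seed = 91)
  grid <- attr(tuned, "grid")
  expect_equal(nrow(grid), 4L)
  best_acc <- grid$accuracy[grid$gamma == tuned$gamma &
                            grid$cost == tuned$cost]
  expect_true(all(best_acc >= grid$accuracy))  # exhaustive grid check
})

test_that("cost = Inf maps to the documented finite surrogate", {
  p <- svmParams()
  expect_equal(p$gamma, 3)
  expect_true(is.infinite(p$cost))
  expect_equal(rsvmcluster:::solverCost(p), 1e6)
  # width parameterization: exponent coefficient is 1/(2 gamma^2)
  expect_equal(rsvmcluster:::solverGamma(p), 1 / 18)
  expect_error(svmParams(gamma = -1), "positive")
})
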
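#' Configuration for a full pipeline run
#'
#' Collects every tunable of the end-to-end experiment with its published
#' default: a 40/2/18 split of 60 subjects, a 500-member cluster with
#' n = 40 bootstrap subjects and d = 62 features per member, RBF width
#' gamma = 3 with a hard margin, member-accuracy threshold 0.75, top-400
#' important features, pool sizes 70..400 and ensemble sizes 5..600.
#'
#' @param n1,n2,n3 training / test / validation sizes (defaults 40, 2, 18).
#' @param k ensemble size (default 500).
#' @param n subjects per member (default 40).
#' @param d features per member (default 62).
#' @param gamma,cost RBF width and margin cost (defaults 3 and `Inf`).
#' @param threshold member-accuracy cut-off for feature extraction
#'   (default 0.75).
#' @param top size of the important-feature ranking (default 400).
#' @param m_values feature-pool sizes (default `seq(70, 400, by = 10)`).
#' @param k_values ensemble sizes for the k sweep
#'   (default `seq(5, 600, by = 5)`).
#' @param seed master seed for the whole run.
#' @param replace bootstrap member subjects with replacement (default TRUE).
#' @return Object of class `runConfig` (validated list).
#' @export
runConfig <- function(n1 = 40L, n2 = 2L, n3 = 18L, k = 500L, n = 40L,
                      d = 62L, gamma = 3, cost = Inf, threshold = 0.75,
                      top = 400L, m_values = seq(70L, 400L, by = 10L),
                      k_values = seq(5L, 600L, by = 5L), seed = 1L,
                      replace = TRUE) {
  cfg <- list(n1 = as.integer(n1), n2 = as.integer(n2), n3 = as.integer(n3),
              k = as.integer(k), n = as.integer(n), d = as.integer(d),
              gamma = gamma, cost = cost, threshold = threshold,
              top = as.integer(top), m_values = as.integer(m_values),
              k_values = as.integer(k_values), seed = as.integer(seed),
              replace = isTRUE(replace))
  if (cfg$n1 < 2L || cfg$n3 < 1L) stop("need n1 >= 2 and n3 >= 1")
  if (cfg$k < 1L || cfg$n < 2L || cfg$d < 1L) stop("invalid k/n/d")
  if (cfg$threshold < 0 || cfg$threshold >= 1) stop("`threshold` must be in [0, 1)")
  if (any(cfg$m_values < cfg$d)) stop("every pool size must be >= d")
  if (any(cfg$m_values > cfg$top)) stop("pool sizes cannot exceed `top`")
  if (length(cfg$k_values) == 0L || is.unsorted(cfg$k_values, strictly = TRUE))
    stop("`k_values` must be strictly ascending")
  structure(cfg, class = "runConfig")
}

#' Run the full classification and feature-selection pipeline
#'
#' Orchestrates the five experiment stages on a cohort: (1) build the main
#' random SVM cluster and compute its validation accuracy, (2) sweep the
#' ensemble size, (3) rank the important features from the high-accuracy
#' members, (4) sweep the feature-pool size to find the optimal feature
#' set, (5) convert the optimal set into region weights.  Every stage uses
#' seeds derived deterministically from `config$seed`, so a rerun with the
#' same inputs reproduces the report exactly.
#'
#' When `out_dir` is given, each artifact is written (as CSV, plus one JSON
#' summary) as soon as it is computed, so partial results survive a failure
#' in a later stage.
#'
#' @param cohort a `syntheticCohort`, a list with `subjects` + `labels`, or
#'   an [fcDataset()] of precomputed features.
#' @param config a [runConfig()].
#' @param out_dir optional report directory.
#' @param motion optional data.frame with columns `max_abs_translation_mm`
#'   and `max_abs_rotation_deg` (one row per subject); subjects failing
#'   [motionQC()] are dropped before the split.
#' @return Object of class `replicationReport`: list with `config`, `split`,
#'   `cluster_accuracy`, `member_accuracy`, `k_curve`, `feature_ranking`,
#'   `pool_sweep`, `optimal_features`, `region_weights`, `n_regions`,
#'   `truth` (when the cohort carries one).
#' @export
runReplication <- function(cohort, config = runConfig(), out_dir = NULL,
                           motion = NULL) {
  stopifnot(inherits(config, "runConfig"))
  truth <- NULL
  if (inherits(cohort, "fcDataset")) {
    ds <- cohort
    n_regions <- round((1 + sqrt(1 + 8 * ncol(ds$features))) / 2)
  } else {
    truth <- cohort$truth
    ds <- connectivityFeatures(cohort)
    n_regions <- ncol(cohort$subjects[[1L]]$data)
  }
  if (!is.null(motion)) {
    keep <- motionQC(motion$max_abs_translation_mm,
                     motion$max_abs_rotation_deg)
    if (!all(keep)) {
      message(sum(!keep), " subject(s) excluded by head-motion QC")
      ds <- fcDataset(ds$features[keep, , drop = FALSE], ds$labels[keep],
                      subject_ids = ds$subject_ids[keep])
    }
  }
  N <- nrow(ds$features)
  sizes <- c(config$n1, config$n2, config$n3)
  if (sum(sizes) != N)
    stop("split sizes (", paste(sizes, collapse = "+"),
         ") must sum to the cohort size (", N, ")")
  params <- svmParams(gamma = config$gamma, cost = config$cost)
  stage_seeds <- deriveSeeds(config$seed, 4L)
  flush <- function(name, df) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }

  split <- splitDataset(ds, sizes = sizes, seed = stage_seeds[1L])

  # stage 1: main cluster
  cluster <- buildCluster(ds, split, n = config$n, d = config$d,
                          k = config$k, params = params,
                          seed = stage_seeds[2L], replace = config$replace)
  cluster <- scoreMembers(cluster, ds, split$validation_idx)
  acc <- clusterAccuracy(cluster, ds, split$validation_idx)
  flush("member_accuracy",
        data.frame(member = seq_len(config$k),
                   accuracy = cluster$member_accuracy))

  # stage 2: ensemble-size sweep
  k_curve <- sweepK(ds, split, n = config$n, d = config$d, params = params,
                    k_values = config$k_values, seed = stage_seeds[3L],
                    replace = config$replace)
  flush("k_curve", k_curve)

  # stage 3: important features
  high <- highAccuracyMembers(cluster, threshold = config$threshold)
  freq <- featureFrequency(cluster, high)
  important <- importantFeatures(freq, top = config$top)
  ranking <- attr(important, "table")
  edge <- connectionEdgeList(ranking$feature, n_regions)
  ranking$region_a <- edge$region_a
  ranking$region_b <- edge$region_b
  flush("feature_ranking", ranking)

  # stage 4: optimal feature set
  m_values <- config$m_values[config$m_values <= length(important)]
  if (length(m_values) == 0L)
    stop("important-feature ranking shorter than every requested pool size")
  pool_sweep <- sweepFeaturePool(ds, split, important, m_values = m_values,
                                 n = config$n, d = config$d, k = config$k,
                                 params = params, seed = stage_seeds[4L],
                                 replace = config$replace)
  flush("pool_sweep", pool_sweep$curve)

  # stage 5: region weights from the optimal feature set
  weights <- computeRegionWeights(pool_sweep$optimal_features, n_regions)
  flush("region_weights", as.data.frame(weights))

  report <- structure(
    list(config = config, split = split,
         cluster_accuracy = acc,
         member_accuracy = cluster$member_accuracy,
         k_curve = k_curve,
         feature_ranking = ranking,
         pool_sweep = pool_sweep,
         optimal_features = pool_sweep$optimal_features,
         region_weights = weights,
         n_regions = n_regions,
         truth = truth),
    class = "replicationReport")
  if (!is.null(out_dir)) writeReportSummary(report, out_dir)
  report
}

writeReportSummary <- function(report, out_dir) {
  s <- list(
    seed = report$config$seed,
    k = report$config$k, n = report$config$n, d = report$config$d,
    gamma = report$config$gamma,
    cost = if (is.infinite(report$config$cost)) "Inf" else report$config$cost,
    threshold = report$config$threshold, top = report$config$top,
    split_sizes = c(report$config$n1, report$config$n2, report$config$n3),
    cluster_accuracy = report$cluster_accuracy,
    mean_member_accuracy = mean(report$member_accuracy),
    best_k = report$k_curve$k[which.max(report$k_curve$accuracy)],
    best_m = report$pool_sweep$best_m,
    best_m_accuracy = report$pool_sweep$best_accuracy,
    top_region = report$region_weights$abbreviation[
      which.max(report$region_weights$weight)])
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(s)
}

#' @export
print.replicationReport <- function(x, ...) {
  cat("Random SVM cluster replication report\n")
  cat(sprintf("  cluster accuracy (validation): %.4f (%.2f%%)\n",
              x$cluster_accuracy, 100 * x$cluster_accuracy))
  cat(sprintf("  mean member accuracy: %.3f\n", mean(x$member_accuracy)))
  cat(sprintf("  k sweep: best k = %d (accuracy %.4f)\n",
              x$k_curve$k[which.max(x$k_curve$accuracy)],
              max(x$k_curve$accuracy)))
  cat(sprintf("  optimal feature set: first %d of %d ranked features (accuracy %.4f)\n",
              x$pool_sweep$best_m, nrow(x$feature_ranking),
              x$pool_sweep$best_accuracy))
  tr <- topRegions(x$region_weights)
  if (nrow(tr))
    cat("  top regions:", paste(utils::head(tr$abbreviation, 5L),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a subjects-by-features matrix as CSV
#'
#' The CSV has one row per subject: a `subject_id` column, a `label`
#' column, then one column per connectivity feature.
#'
#' @param ds an [fcDataset()].
#' @param file path to write to / read from.
#' @return `readFeatures()` returns an [fcDataset()].
#' @export
writeFeatures <- function(ds, file) {
  df <- data.frame(subject_id = ds$subject_ids,
                   label = as.character(ds$labels),
                   ds$features, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeFeatures
#' @param positive_class optional label value to treat as the positive
#'   (patient) class; defaults to the first level alphabetically.
#' @export
readFeatures <- function(file, positive_class = NULL) {
  df <- utils::read.csv(file, check.names = FALSE)
  labels <- factor(df$label)
  if (!is.null(positive_class))
    labels <- stats::relevel(labels, ref = positive_class)
  feats <- as.matrix(df[, !(names(df) %in% c("subject_id", "label")),
                        drop = FALSE])
  fcDataset(feats, labels, subject_ids = df$subject_id)
}
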
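#' Select the high-accuracy ensemble members
#'
#' Members whose individual accuracy strictly exceeds `threshold`, ordered
#' by accuracy from largest to smallest (ties keep member order).  Member
#' accuracies must have been computed first ([scoreMembers()]) or be passed
#' explicitly.
#'
#' @param cluster a scored [buildCluster()] result.
#' @param threshold accuracy cut-off (default 0.75); strictly greater-than,
#'   so a member exactly at the threshold is excluded.
#' @param accuracies optional numeric vector overriding the stored member
#'   accuracies.
#' @return Integer vector of member indices, sorted by accuracy descending.
#' @export
highAccuracyMembers <- function(cluster, threshold = 0.75, accuracies = NULL) {
  acc <- accuracies %||% memberAccuracyVector(cluster)
  if (anyNA(acc))
    stop("member accuracies not computed; run scoreMembers() first")
  keep <- which(acc > threshold)
  if (length(keep) == 0L)
    stop("no member exceeds accuracy threshold ", threshold,
         "; consider lowering the threshold")
  keep[order(acc[keep], decreasing = TRUE)]
}

#' Feature occurrence counts across selected members
#'
#' Stacks the feature subsets of the given members into one feature matrix
#' and counts how often each feature occurs.  The counts sum to
#' (number of members) x d by construction.
#'
#' @param cluster a [buildCluster()] result.
#' @param member_idx indices of the members to pool (e.g. from
#'   [highAccuracyMembers()]); default: all members.
#' @return Object of class `featureFrequencyTable`: data.frame with columns
#'   `feature` and `count`, sorted by count descending then feature index
#'   ascending, with attributes `n_members` and `d`.
#' @export
featureFrequency <- function(cluster, member_idx = seq_len(cluster$k)) {
  if (length(member_idx) == 0L) stop("`member_idx` must be non-empty")
  all_feats <- unlist(lapply(cluster$members[member_idx], `[[`, "feature_idx"))
  tab <- table(all_feats)
  out <- data.frame(feature = as.integer(names(tab)),
                    count = as.integer(tab))
  out <- out[order(-out$count, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_members = length(member_idx), d = cluster$d,
            class = c("featureFrequencyTable", "data.frame"))
}

#' Rank the "important features"
#'
#' The `top` most frequent features among the pooled subsets of the
#' high-accuracy members, in frequency order from high to low.  Equal counts
#' are broken by ascending feature index, which makes every ranking a prefix
#' of any longer one.
#'
#' @param freq a [featureFrequency()] table.
#' @param top maximum number of features to keep (default 400).
#' @return Integer vector of feature indices (length `min(top, available)`;
#'   a warning is raised when fewer than `top` distinct features exist),
#'   with the table row for each kept feature as attribute `"table"`.
#' @export
importantFeatures <- function(freq, top = 400L) {
  stopifnot(inherits(freq, "featureFrequencyTable"))
  if (nrow(freq) < top)
    warning("only ", nrow(freq), " distinct features available (< top = ",
            top, "); returning all")
  freq <- freq[order(-freq$count, freq$feature), , drop = FALSE]
  keep <- freq[seq_len(min(top, nrow(freq))), , drop = FALSE]
  structure(keep$feature, table = keep, threshold_top = as.integer(top))
}

#' Accuracy as a function of the feature-pool size
#'
#' For each pool size m, restricts the members' feature sampling to the
#' first m entries of the important-feature ranking (each member still draws
#' `d` features), rebuilds the ensemble with a fresh derived seed, and
#' scores it on the validation set.  The optimal feature set is the first
#' `best_m` ranked features, where `best_m` is the smallest pool size
#' attaining the maximum accuracy.
#'
#' @inheritParams buildCluster
#' @param important integer vector of ranked feature indices
#'   ([importantFeatures()]).
#' @param m_values pool sizes to try, each within `[d, length(important)]`
#'   (default `seq(70, 400, by = 10)`).
#' @return Object of class `featurePoolSweep`: list with `curve`
#'   (data.frame m, accuracy), `best_m`, `best_accuracy`,
#'   `optimal_features`.
#' @export
sweepFeaturePool <- function(ds, split, important,
                             m_values = seq(70L, 400L, by = 10L),
                             n = length(split$train_idx), d = 62L, k = 500L,
                             params = svmParams(), seed = 1L, replace = TRUE) {
  m_values <- as.integer(m_values)
  if (length(m_values) == 0L) stop("`m_values` must be non-empty")
  if (any(m_values < d))
    stop("every pool size must be at least d = ", d)
  if (any(m_values > length(important)))
    stop("pool sizes exceed the important-feature ranking length (",
         length(important), ")")
  seeds <- deriveSeeds(seed, length(m_values))
  acc <- vapply(seq_along(m_values), function(idx) {
    cl <- buildCluster(ds, split, n = n, d = d, k = k, params = params,
                       seed = seeds[idx], replace = replace,
                       feature_pool = important[seq_len(m_values[idx])])
    clusterAccuracy(cl, ds, split$validation_idx)
  }, numeric(1L))
  best_i <- which(acc == max(acc))[1L]   # ties -> smallest m (ascending grid)
  structure(list(curve = data.frame(m = m_values, accuracy = acc),
                 best_m = m_values[best_i], best_accuracy = acc[best_i],
                 optimal_features = important[seq_len(m_values[best_i])]),
            class = "featurePoolSweep")
}

#' @export
print.featurePoolSweep <- function(x, ...) {
  cat("Feature-pool sweep over", nrow(x$curve), "pool sizes:",
      "best m =", x$best_m,
      sprintf("(validation accuracy %.4f)\n", x$best_accuracy))
  invisible(x)
}
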
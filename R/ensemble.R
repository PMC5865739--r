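#' Subjects-by-features dataset for classification
#'
#' @param features numeric N x P matrix of connectivity features, no missing
#'   values.
#' @param labels factor (or coercible) of length N with exactly two levels;
#'   the first level is the positive (patient) class.
#' @param subject_ids character vector of length N; defaults to the feature
#'   matrix row names or `S001`, `S002`, ...
#' @return Object of class `fcDataset`: list with `features`, `labels`,
#'   `subject_ids`.
#' @export
fcDataset <- function(features, labels, subject_ids = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("`features` must be numeric")
  if (anyNA(features)) stop("`features` contains missing values")
  if (nrow(features) < 4L) stop("need at least 4 subjects")
  labels <- as.factor(labels)
  labels <- factor(labels, levels = levels(labels))  # drop nothing, keep order
  if (nlevels(labels) != 2L) stop("`labels` must have exactly 2 levels")
  if (length(labels) != nrow(features))
    stop("`labels` length must match rows of `features`")
  if (any(table(labels) == 0L)) stop("both classes must be present")
  subject_ids <- subject_ids %||% rownames(features) %||%
    sprintf("S%03d", seq_len(nrow(features)))
  structure(list(features = features, labels = labels,
                 subject_ids = as.character(subject_ids)),
            class = "fcDataset")
}

#' @export
print.fcDataset <- function(x, ...) {
  tb <- table(x$labels)
  cat("Functional-connectivity dataset:", nrow(x$features), "subjects x",
      ncol(x$features), "features (",
      paste(names(tb), tb, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' SVM hyper-parameters for ensemble members
#'
#' Every member uses an RBF kernel `k(u, v) = exp(-||u - v||^2 / (2 gamma^2))`
#' with width parameter `gamma` (default 3) and a soft-margin cost
#' (default `Inf`, i.e. a hard margin).  Because the underlying solver
#' requires a finite cost, `Inf` is mapped to the surrogate
#' `cost_surrogate` (default 1e6).
#'
#' @param gamma kernel width, > 0 (default 3).
#' @param cost soft-margin cost, > 0 or `Inf` (default `Inf`).
#' @param cost_surrogate finite stand-in used when `cost = Inf`.
#' @return Object of class `svmParams`.
#' @export
svmParams <- function(gamma = 3, cost = Inf, cost_surrogate = 1e6) {
  if (!is.numeric(gamma) || gamma <= 0) stop("`gamma` must be positive")
  if (!is.numeric(cost) || cost <= 0) stop("`cost` must be positive or Inf")
  structure(list(kernel = "RBF", gamma = gamma, cost = cost,
                 cost_surrogate = cost_surrogate),
            class = "svmParams")
}

#' @export
print.svmParams <- function(x, ...) {
  cat(sprintf("RBF-SVM params: gamma (width) = %g, cost = %g%s\n",
              x$gamma, x$cost,
              if (is.infinite(x$cost))
                sprintf(" (solver surrogate %g)", x$cost_surrogate) else ""))
  invisible(x)
}

# gamma is the kernel *width*; the solver wants the exponent coefficient.
solverGamma <- function(params) 1 / (2 * params$gamma^2)
solverCost  <- function(params)
  if (is.infinite(params$cost)) params$cost_surrogate else params$cost

#' Split a dataset into training, test and validation sets
#'
#' Uniformly random disjoint partition of the N subjects into a training set
#' (used to train ensemble members), a test set (used to tune
#' hyper-parameters) and a validation set (used to score members and the
#' ensemble).  The split is resampled (up to `max_retries` times) until the
#' training and validation sets each contain both classes; sets of size zero
#' are exempt.
#'
#' @param ds an [fcDataset()].
#' @param sizes integer vector `c(n_train, n_test, n_validation)` summing
#'   to N.  Default `c(40, 2, 18)`.
#' @param seed RNG seed.
#' @param max_retries resample bound for class coverage (default 100).
#' @return Object of class `splitSpec`: list with `train_idx`, `test_idx`,
#'   `validation_idx`, `sizes`, `seed`.
#' @export
splitDataset <- function(ds, sizes = c(40L, 2L, 18L), seed = 1L,
                         max_retries = 100L) {
  stopifnot(inherits(ds, "fcDataset"))
  N <- nrow(ds$features)
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || any(sizes < 0L))
    stop("`sizes` must be 3 non-negative counts")
  if (sum(sizes) != N)
    stop("`sizes` must sum to the number of subjects (", N, ")")
  covered <- function(idx)
    length(idx) == 0L || nlevels(droplevels(ds$labels[idx])) == 2L
  withSeed(seed, {
    for (attempt in seq_len(max_retries)) {
      perm <- sample.int(N)
      train_idx <- sort(perm[seq_len(sizes[1L])])
      test_idx <- sort(perm[sizes[1L] + seq_len(sizes[2L])])
      validation_idx <- sort(perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])])
      if (covered(train_idx) && covered(validation_idx)) {
        return(structure(list(train_idx = train_idx, test_idx = test_idx,
                              validation_idx = validation_idx,
                              sizes = sizes, seed = as.integer(seed)),
                         class = "splitSpec"))
      }
    }
    stop("could not draw a split with both classes in the training and ",
         "validation sets after ", max_retries, " attempts")
  })
}

#' @export
print.splitSpec <- function(x, ...) {
  cat("Split: train", length(x$train_idx), "/ test", length(x$test_idx),
      "/ validation", length(x$validation_idx), "(seed", x$seed, ")\n")
  invisible(x)
}

# Train one member SVM on given sample/feature subsets.
trainMember <- function(ds, sample_idx, feature_idx, params) {
  e1071::svm(x = ds$features[sample_idx, feature_idx, drop = FALSE],
             y = ds$labels[sample_idx],
             kernel = "radial", gamma = solverGamma(params),
             cost = solverCost(params), scale = FALSE)
}

#' Build a random SVM cluster
#'
#' Trains `k` member SVMs.  Member t draws `n` subjects from the training
#' set (a bootstrap draw with replacement by default; set `replace = FALSE`
#' for subsampling) and `d` distinct features uniformly from the feature
#' pool, then fits an RBF SVM on that subset alone.  A member whose sampled
#' subjects are single-class is redrawn up to 20 times, then an error is
#' raised.  The whole construction is reproducible from `seed`: per-member
#' seeds are derived up-front from the master seed, so member t is identical
#' regardless of how many members are built.
#'
#' @param ds an [fcDataset()].
#' @param split a [splitDataset()] result.
#' @param n subjects per member (default: size of the training set).
#' @param d features per member (default 62 when the pool has 4005 features,
#'   matching the published configuration, else `round(sqrt(pool size))`).
#' @param k number of members (default 500).
#' @param params an [svmParams()].
#' @param seed master RNG seed.
#' @param replace bootstrap with replacement? (default TRUE).
#' @param feature_pool optional integer vector restricting the features the
#'   members may draw from (default: all columns).
#' @return Object of class `randomSvmCluster`: list with `members` (each a
#'   list with `sample_idx`, `feature_idx`, `model`, `seed`, `accuracy`),
#'   `params`, `n`, `d`, `k`, `seed`, `replace`, `feature_pool`,
#'   `positive_class`, `levels`.
#' @export
buildCluster <- function(ds, split, n = length(split$train_idx), d = NULL,
                         k = 500L, params = svmParams(), seed = 1L,
                         replace = TRUE, feature_pool = NULL) {
  stopifnot(inherits(ds, "fcDataset"), inherits(split, "splitSpec"))
  P <- ncol(ds$features)
  pool <- as.integer(feature_pool %||% seq_len(P))
  if (any(pool < 1L | pool > P)) stop("`feature_pool` indices out of range")
  d <- as.integer(d %||% if (length(pool) == 4005L) 62L
                         else max(1L, round(sqrt(length(pool)))))
  if (d > length(pool))
    stop("`d` (", d, ") exceeds the feature pool size (", length(pool), ")")
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be at least 1")
  train <- split$train_idx
  if (length(train) < 2L) stop("training set too small")
  if (!replace && n > length(train))
    stop("`n` exceeds training-set size and `replace` is FALSE")
  member_seeds <- deriveSeeds(seed, k)
  members <- lapply(seq_len(k), function(t) {
    withSeed(member_seeds[t], {
      sample_idx <- NULL
      for (try in seq_len(20L)) {
        s <- sample(train, n, replace = replace)
        if (nlevels(droplevels(ds$labels[s])) == 2L) { sample_idx <- s; break }
      }
      if (is.null(sample_idx))
        stop("member ", t, ": sampled subjects single-class after 20 redraws; ",
             "the training set is too imbalanced for n = ", n)
      feature_idx <- sort(sample(pool, d))
      list(sample_idx = sample_idx, feature_idx = feature_idx,
           model = trainMember(ds, sample_idx, feature_idx, params),
           seed = member_seeds[t], accuracy = NA_real_)
    })
  })
  structure(list(members = members, params = params, n = as.integer(n),
                 d = d, k = k, seed = as.integer(seed), replace = replace,
                 feature_pool = pool,
                 positive_class = levels(ds$labels)[1L],
                 levels = levels(ds$labels)),
            class = "randomSvmCluster")
}

#' @export
print.randomSvmCluster <- function(x, ...) {
  cat("Random SVM cluster:", x$k, "members, n =", x$n, ", d =", x$d,
      "of", length(x$feature_pool), "pooled features;",
      sprintf("gamma = %g, cost = %g\n", x$params$gamma, x$params$cost))
  if (!all(is.na(vapply(x$members, `[[`, numeric(1L), "accuracy"))))
    cat("  member accuracy: mean",
        round(mean(memberAccuracyVector(x)), 3), "\n")
  invisible(x)
}

memberAccuracyVector <- function(cluster)
  vapply(cluster$members, `[[`, numeric(1L), "accuracy")

# Member predictions and signed decision values on rows of `newdata`
# (full-width feature matrix).  Decision values are oriented so that
# positive means the cluster's positive class.
memberVotes <- function(cluster, newdata) {
  newdata <- rbind(newdata)  # keep matrix shape for a single vector
  votes <- matrix(NA_character_, nrow(newdata), cluster$k)
  dvals <- matrix(NA_real_, nrow(newdata), cluster$k)
  for (t in seq_len(cluster$k)) {
    m <- cluster$members[[t]]
    pr <- stats::predict(m$model,
                         newdata[, m$feature_idx, drop = FALSE],
                         decision.values = TRUE)
    votes[, t] <- as.character(pr)
    dv <- drop(attr(pr, "decision.values"))
    # column name "lev1/lev2": positive decision value favours lev1
    lev1 <- sub("/.*$", "", colnames(attr(pr, "decision.values"))[1L])
    dvals[, t] <- if (identical(lev1, cluster$positive_class)) dv else -dv
  }
  list(votes = votes, decision_values = dvals)
}

#' Majority-vote prediction from a random SVM cluster
#'
#' Every member classifies the sample using its own feature subset; the
#' class with the strictly larger vote count wins.  An exact tie (possible
#' for even `k`) is broken by the sign of the summed member decision values;
#' a zero sum predicts the negative (control) class.
#'
#' @param object a [buildCluster()] result.
#' @param newdata numeric matrix (rows = samples) with the full feature
#'   dimensionality, or a single feature vector.
#' @param type `"class"` (default) for the predicted labels, `"votes"` to
#'   also return the per-class vote counts.
#' @param ... unused.
#' @return factor of predicted labels; for `type = "votes"`, a list with
#'   `class` and a samples x 2 `votes` count matrix.
#' @export
predict.randomSvmCluster <- function(object, newdata, type = c("class", "votes"),
                                     ...) {
  type <- match.arg(type)
  mv <- memberVotes(object, newdata)
  pos <- object$positive_class
  neg <- setdiff(object$levels, pos)
  npos <- rowSums(mv$votes == pos)
  nneg <- object$k - npos
  lab <- ifelse(npos > nneg, pos,
         ifelse(nneg > npos, neg,
                ifelse(rowSums(mv$decision_values) > 0, pos, neg)))
  lab <- factor(lab, levels = object$levels)
  if (type == "class") return(lab)
  votes <- cbind(npos, nneg)
  colnames(votes) <- c(pos, neg)
  list(class = lab, votes = votes)
}

#' Ensemble accuracy on an evaluation set
#'
#' Fraction of evaluation subjects whose majority-vote prediction matches
#' the true label (the Nc/N3 criterion when evaluated on the validation
#' set).
#'
#' @param cluster a [buildCluster()] result.
#' @param ds the [fcDataset()] the cluster indexes into.
#' @param eval_idx non-empty subject indices to score on.
#' @return accuracy in \[0, 1\].
#' @export
clusterAccuracy <- function(cluster, ds, eval_idx) {
  if (length(eval_idx) == 0L) stop("`eval_idx` must be non-empty")
  pred <- predict(cluster, ds$features[eval_idx, , drop = FALSE])
  mean(as.character(pred) == as.character(ds$labels[eval_idx]))
}

#' Per-member accuracies
#'
#' Scores every member SVM independently on the evaluation set, using only
#' that member's feature subset.
#'
#' @inheritParams clusterAccuracy
#' @return numeric vector of length `k`.
#' @seealso [scoreMembers()] to store the accuracies inside the cluster.
#' @export
memberAccuracies <- function(cluster, ds, eval_idx) {
  if (length(eval_idx) == 0L) stop("`eval_idx` must be non-empty")
  truth <- as.character(ds$labels[eval_idx])
  mv <- memberVotes(cluster, ds$features[eval_idx, , drop = FALSE])
  colMeans(mv$votes == matrix(truth, length(truth), cluster$k))
}

#' Store member accuracies inside a cluster
#'
#' @inheritParams clusterAccuracy
#' @return The cluster with each member's `accuracy` field (and
#'   `member_accuracy` vector) filled in.
#' @export
scoreMembers <- function(cluster, ds, eval_idx) {
  acc <- memberAccuracies(cluster, ds, eval_idx)
  for (t in seq_len(cluster$k)) cluster$members[[t]]$accuracy <- acc[t]
  cluster$member_accuracy <- acc
  cluster
}

#' Ensemble accuracy as a function of the number of members
#'
#' Builds one cluster per entry of `k_values` (each with a fresh seed
#' derived deterministically from `seed`) and scores it on the validation
#' set, tracing how accuracy stabilizes as the ensemble grows.
#'
#' @inheritParams buildCluster
#' @param k_values ascending positive ensemble sizes
#'   (default `seq(5, 600, by = 5)`).
#' @return data.frame with columns `k` and `accuracy`.
#' @export
sweepK <- function(ds, split, n = length(split$train_idx), d = NULL,
                   params = svmParams(), k_values = seq(5L, 600L, by = 5L),
                   seed = 1L, replace = TRUE, feature_pool = NULL) {
  if (length(k_values) == 0L) stop("`k_values` must be non-empty")
  if (is.unsorted(k_values, strictly = TRUE))
    stop("`k_values` must be strictly ascending")
  seeds <- deriveSeeds(seed, length(k_values))
  acc <- vapply(seq_along(k_values), function(idx) {
    cl <- buildCluster(ds, split, n = n, d = d, k = k_values[idx],
                       params = params, seed = seeds[idx], replace = replace,
                       feature_pool = feature_pool)
    clusterAccuracy(cl, ds, split$validation_idx)
  }, numeric(1L))
  data.frame(k = as.integer(k_values), accuracy = acc)
}

#' Tune SVM hyper-parameters on the test set
#'
#' Builds one cluster per (gamma, cost) grid point — all from the same
#' derived seed, so clusters differ only in the hyper-parameters — and
#' returns the pair maximizing accuracy on the test set.  Ties are broken
#' toward smaller gamma, then smaller cost.
#'
#' @inheritParams buildCluster
#' @param gamma_grid,cost_grid non-empty numeric grids (cost may include
#'   `Inf`).
#' @return The winning [svmParams()]; the full grid with accuracies is
#'   attached as attribute `"grid"`.
#' @export
tuneParams <- function(ds, split, gamma_grid, cost_grid,
                       n = length(split$train_idx), d = NULL, k = 100L,
                       seed = 1L) {
  if (length(gamma_grid) == 0L || length(cost_grid) == 0L)
    stop("parameter grids must be non-empty")
  if (length(split$test_idx) == 0L) stop("test set is empty")
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid)
  sub_seed <- deriveSeeds(seed, 1L)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(r) {
    cl <- buildCluster(ds, split, n = n, d = d, k = k,
                       params = svmParams(gamma = grid$gamma[r],
                                          cost = grid$cost[r]),
                       seed = sub_seed)
    clusterAccuracy(cl, ds, split$test_idx)
  }, numeric(1L))
  best <- grid[order(-grid$accuracy, grid$gamma, grid$cost), ][1L, ]
  out <- svmParams(gamma = best$gamma, cost = best$cost)
  attr(out, "grid") <- grid
  out
}
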
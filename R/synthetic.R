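#' Specification of a synthetic two-group cohort
#'
#' Describes a two-group cohort of regional time series in which a chosen
#' subset of region pairs ("planted" connections) has a different target
#' correlation in each group, against a common background correlation.
#' Group sizes, region count and series length default to the scale of a
#' typical AD-vs-control resting-state study: 25 + 35 subjects, 90 AAL
#' regions, 120 retained time points.
#'
#' Each group's target correlation matrix is the background matrix with the
#' planted entries overwritten.  If a target matrix is not positive
#' semi-definite it is repaired by clipping eigenvalues at 1e-8 and
#' renormalizing to unit diagonal; if the repair moves any planted
#' correlation by more than 0.05 an error names the offending pairs.
#'
#' @param n_group_a,n_group_b subjects per group (>= 2 each).
#' @param n_regions number of regions R (>= 3; default 90).
#' @param n_timepoints series length T (>= 10; default 120).
#' @param planted_pairs data.frame with columns `i`, `j` (1-based region
#'   indices, i < j), `corr_a`, `corr_b` (target correlations in each group,
#'   in \[-1, 1\]); or NULL for none.  See [plantRandomPairs()].
#' @param baseline_corr background correlation shared by all unplanted pairs
#'   in both groups (default 0.1, a typical resting-state background level).
#' @param noise_sd standard deviation of additive i.i.d. observation noise
#'   (default 0.2).  Note the noise attenuates every observed correlation by
#'   the factor 1/(1 + noise_sd^2) relative to its target.
#' @param seed integer RNG seed.
#' @return Object of class `syntheticSpec` (a validated list).
#' @export
syntheticSpec <- function(n_group_a = 25L, n_group_b = 35L, n_regions = 90L,
                          n_timepoints = 120L, planted_pairs = NULL,
                          baseline_corr = 0.1, noise_sd = 0.2, seed = 1L) {
  if (n_group_a < 2L || n_group_b < 2L) stop("each group needs at least 2 subjects")
  if (n_regions < 3L) stop("`n_regions` must be at least 3")
  if (n_timepoints < 10L) stop("`n_timepoints` must be at least 10")
  if (abs(baseline_corr) >= 1) stop("`baseline_corr` must lie in (-1, 1)")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(i = integer(), j = integer(),
                                corr_a = numeric(), corr_b = numeric())
  }
  planted_pairs <- as.data.frame(planted_pairs)
  need <- c("i", "j", "corr_a", "corr_b")
  if (!all(need %in% names(planted_pairs)))
    stop("`planted_pairs` needs columns i, j, corr_a, corr_b")
  pp <- planted_pairs[need]
  if (nrow(pp)) {
    if (any(pp$i < 1L) || any(pp$j <= pp$i) || any(pp$j > n_regions))
      stop("planted pairs must satisfy 1 <= i < j <= n_regions")
    if (any(abs(pp$corr_a) > 1) || any(abs(pp$corr_b) > 1))
      stop("planted correlations must lie in [-1, 1]")
    if (anyDuplicated(pp[c("i", "j")])) stop("duplicated planted pairs")
    pp <- pp[order(pp$i, pp$j), , drop = FALSE]
    rownames(pp) <- NULL
  }
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints),
                 planted_pairs = pp,
                 baseline_corr = baseline_corr,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' @export
print.syntheticSpec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_group_a, "+", x$n_group_b, "subjects,",
      x$n_regions, "regions,", x$n_timepoints, "time points,",
      nrow(x$planted_pairs), "planted pair(s)\n")
  invisible(x)
}

#' Draw a random set of planted group-differential pairs
#'
#' Convenience constructor for the `planted_pairs` slot of a
#' [syntheticSpec()]: `n_pairs` region pairs over disjoint regions (no two
#' pairs share a region), all given correlation `corr_a` in group A and
#' `corr_b` in group B.  Disjointness keeps the target correlation matrices
#' positive semi-definite for moderate correlations — a region shared by
#' several strong planted edges whose other endpoints are only weakly
#' coupled can make the target infeasible — and guarantees the
#' group difference stays confined to exactly the planted entries.
#' Arbitrary (including region-sharing) pair sets can still be passed to
#' [syntheticSpec()] directly.
#'
#' @param n_pairs number of pairs (default 20; at most `n_regions / 2`).
#' @param corr_a,corr_b target correlations (defaults 0.6 and -0.2).
#' @param n_regions region count (default 90).
#' @param seed RNG seed for the pair draw.
#' @return data.frame suitable for `syntheticSpec(planted_pairs = ...)`.
#' @export
plantRandomPairs <- function(n_pairs = 20L, corr_a = 0.6, corr_b = -0.2,
                             n_regions = 90L, seed = 1L) {
  if (2L * n_pairs > n_regions)
    stop("disjoint pairs need 2 * n_pairs <= n_regions")
  regions <- withSeed(seed, sample.int(n_regions, 2L * n_pairs))
  i <- pmin(regions[seq_len(n_pairs)], regions[n_pairs + seq_len(n_pairs)])
  j <- pmax(regions[seq_len(n_pairs)], regions[n_pairs + seq_len(n_pairs)])
  ord <- order(i, j)
  data.frame(i = i[ord], j = j[ord], corr_a = corr_a, corr_b = corr_b)
}

# Target correlation matrix for one group; repaired to PSD if needed.
# Returns the matrix with attribute "repaired" (logical).
groupTargetMatrix <- function(spec, group = c("a", "b")) {
  group <- match.arg(group)
  col <- if (group == "a") "corr_a" else "corr_b"
  R <- spec$n_regions
  S <- matrix(spec$baseline_corr, R, R)
  diag(S) <- 1
  pp <- spec$planted_pairs
  for (r in seq_len(nrow(pp))) {
    S[pp$i[r], pp$j[r]] <- S[pp$j[r], pp$i[r]] <- pp[[col]][r]
  }
  repaired <- FALSE
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-8) {
    repaired <- TRUE
    v <- pmax(e$values, 1e-8)
    S2 <- e$vectors %*% (v * t(e$vectors))
    Dn <- 1 / sqrt(diag(S2))
    S2 <- S2 * outer(Dn, Dn)
    if (nrow(pp)) {
      achieved <- S2[cbind(pp$i, pp$j)]
      dev <- abs(achieved - pp[[col]])
      if (any(dev > 0.05)) {
        bad <- pp[dev > 0.05, , drop = FALSE]
        stop("target correlation matrix for group ", toupper(group),
             " is not positive semi-definite and cannot be repaired within ",
             "tolerance 0.05 for pair(s): ",
             paste0("(", bad$i, ",", bad$j, ")", collapse = ", "))
      }
    }
    S <- S2
  }
  attr(S, "repaired") <- repaired
  S
}

#' Generate a synthetic two-group cohort of ROI time series
#'
#' Each subject's T x R series is drawn from a multivariate normal with the
#' subject's group target correlation matrix (series = i.i.d. standard
#' normal draws multiplied by its Cholesky factor), plus independent
#' Gaussian observation noise of standard deviation `noise_sd`.  The same
#' spec and seed always reproduce the cohort exactly.
#'
#' @param spec a [syntheticSpec()].
#' @return Object of class `syntheticCohort`: list with
#'   \describe{
#'     \item{subjects}{list of [roiTimeSeries()], group A first}
#'     \item{labels}{factor with levels `c("A", "B")`; A (the patient-like
#'       group) is the positive class}
#'     \item{truth}{sorted connectivity-feature indices of the planted pairs}
#'     \item{spec}{the generating spec}
#'     \item{repaired}{logical: whether either group's target matrix needed
#'       a PSD repair}
#'   }
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  Sa <- groupTargetMatrix(spec, "a")
  Sb <- groupTargetMatrix(spec, "b")
  repaired <- attr(Sa, "repaired") || attr(Sb, "repaired")
  La <- chol(Sa + diag(1e-10, spec$n_regions))
  Lb <- chol(Sb + diag(1e-10, spec$n_regions))
  Tn <- spec$n_timepoints; R <- spec$n_regions
  labels <- factor(rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b)),
                   levels = c("A", "B"))
  rlab <- if (R == 90L) aal90Regions()$abbreviation else paste0("R", seq_len(R))
  subjects <- withSeed(spec$seed, {
    lapply(seq_along(labels), function(s) {
      L <- if (labels[s] == "A") La else Lb
      X <- matrix(stats::rnorm(Tn * R), Tn, R) %*% L
      if (spec$noise_sd > 0)
        X <- X + matrix(stats::rnorm(Tn * R, sd = spec$noise_sd), Tn, R)
      roiTimeSeries(X, subject_id = sprintf("S%03d", s), region_labels = rlab)
    })
  })
  truth <- if (nrow(spec$planted_pairs)) {
    sort(indexOfPair(spec$planted_pairs$i, spec$planted_pairs$j, R))
  } else integer()
  structure(list(subjects = subjects, labels = labels, truth = truth,
                 spec = spec, repaired = repaired),
            class = "syntheticCohort")
}

#' @export
print.syntheticCohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$subjects), "subjects (",
      sum(x$labels == levels(x$labels)[1L]), "A /",
      sum(x$labels == levels(x$labels)[2L]), "B ),",
      x$spec$n_regions, "regions,", x$spec$n_timepoints, "time points;",
      length(x$truth), "planted connection(s)",
      if (x$repaired) "[PSD repair applied]" else "", "\n")
  invisible(x)
}

#' Write a cohort to disk as plain CSV files
#'
#' Writes one T x R CSV per subject (header = region labels), a cohort
#' manifest (`manifest.csv`: subject_id, file, label) and, for synthetic
#' cohorts, a truth file (`truth.csv`) listing the planted connectivity
#' feature indices.
#'
#' @param cohort a `syntheticCohort`, or a list with elements `subjects`
#'   and `labels`.
#' @param dir output directory (created if missing).
#' @return The manifest data.frame, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(cohort$subjects, function(s) {
    f <- paste0(s$subject_id, ".csv")
    utils::write.csv(as.data.frame(s$data), file.path(dir, f),
                     row.names = FALSE)
    f
  }, character(1L))
  manifest <- data.frame(
    subject_id = vapply(cohort$subjects, function(s) s$subject_id, character(1L)),
    file = files, label = as.character(cohort$labels))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(data.frame(feature_index = cohort$truth),
                     file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing `manifest.csv` and the per-subject CSVs.
#' @return List with `subjects` (list of [roiTimeSeries()]), `labels`
#'   (factor) and `truth` (integer vector, or NULL if no truth file).
#' @export
readCohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(manifest)), function(r) {
    readRoiTimeSeries(file.path(dir, manifest$file[r]),
                      subject_id = manifest$subject_id[r])
  })
  truth_file <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_file))
    utils::read.csv(truth_file)$feature_index else NULL
  list(subjects = subjects, labels = factor(manifest$label), truth = truth)
}
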
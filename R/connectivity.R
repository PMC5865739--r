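#' ROI time-series container
#'
#' Bundles one subject's regional time series: a numeric matrix with one row
#' per time point and one column per brain region, plus region labels.
#'
#' @param data numeric T x R matrix (T time points, R regions), no missing
#'   values, at least 3 rows and 3 columns.
#' @param subject_id character scalar identifying the subject.
#' @param region_labels character vector of R region names; defaults to the
#'   matrix column names, or to the packaged AAL-90 abbreviations when R = 90.
#' @return An object of class `roiTimeSeries`: a list with elements
#'   `subject_id`, `data` (with `region_labels` as column names) and
#'   `region_labels`.
#' @seealso [pearsonMatrix()], [connectivityFeatures()]
#' @export
roiTimeSeries <- function(data, subject_id = "subject", region_labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (nrow(data) < 3L) stop("need at least 3 time points")
  if (ncol(data) < 3L) stop("need at least 3 regions")
  if (anyNA(data) || any(!is.finite(data))) stop("`data` contains missing or non-finite values")
  if (is.null(region_labels)) {
    region_labels <- colnames(data)
    if (is.null(region_labels)) {
      region_labels <- if (ncol(data) == 90L) aal90Regions()$abbreviation
                       else paste0("R", seq_len(ncol(data)))
    }
  }
  if (length(region_labels) != ncol(data))
    stop("`region_labels` must have one entry per column of `data`")
  colnames(data) <- region_labels
  structure(list(subject_id = as.character(subject_id),
                 data = data, region_labels = as.character(region_labels)),
            class = "roiTimeSeries")
}

#' @export
print.roiTimeSeries <- function(x, ...) {
  cat("ROI time series: subject", x$subject_id, "-",
      nrow(x$data), "time points x", ncol(x$data), "regions\n")
  invisible(x)
}

#' Region-by-region Pearson correlation matrix
#'
#' Computes the sample Pearson correlation between every pair of regional
#' time series — the functional-connectivity matrix of one subject.
#'
#' @param ts an [roiTimeSeries()] object, or a plain numeric T x R matrix.
#' @return Symmetric R x R correlation matrix with unit diagonal and the
#'   region labels as dimnames.
#' @export
pearsonMatrix <- function(ts) {
  if (inherits(ts, "roiTimeSeries")) ts <- ts$data
  ts <- as.matrix(ts)
  v <- apply(ts, 2L, function(col) sum((col - mean(col))^2))
  if (any(v == 0)) {
    bad <- colnames(ts)[v == 0] %||% which(v == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "),
         " - Pearson correlation undefined")
  }
  m <- stats::cor(ts)
  # guard against numerical overshoot beyond [-1, 1]
  m[m > 1] <- 1; m[m < -1] <- -1
  diag(m) <- 1
  m
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Flattens a symmetric R x R matrix into the length R(R-1)/2 connectivity
#' feature vector, in the fixed row-major pair order
#' (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R).  For the 90-region AAL
#' parcellation this yields 4005 features.  The ordering is the package-wide
#' convention; [pairOfIndex()] and [indexOfPair()] convert between feature
#' indices and region pairs.
#'
#' @param mat symmetric numeric matrix with unit diagonal (tolerance 1e-10 on
#'   symmetry, 1e-8 on the diagonal).
#' @return Named numeric vector of length R(R-1)/2; names are
#'   `"<regionA>__<regionB>"` when `mat` has dimnames.
#' @export
vectorizeUpper <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("`mat` must be square")
  if (max(abs(mat - t(mat))) > 1e-10) stop("`mat` is asymmetric beyond tolerance 1e-10")
  if (max(abs(diag(mat) - 1)) > 1e-8) stop("`mat` must have unit diagonal")
  tm <- t(mat)
  v <- tm[lower.tri(tm)]   # row-major upper triangle of `mat`
  if (!is.null(rownames(mat))) {
    R <- nrow(mat)
    pr <- pairOfIndex(seq_along(v), R)
    names(v) <- paste0(rownames(mat)[pr[, 1L]], "__", rownames(mat)[pr[, 2L]])
  }
  v
}

#' Convert between connectivity feature indices and region pairs
#'
#' The connectivity vector enumerates region pairs (i, j), i < j, row-major:
#' (1,2), (1,3), ..., (1,R), (2,3), ...  `pairOfIndex()` maps feature indices
#' to pairs; `indexOfPair()` is its inverse.  All indices are 1-based.
#'
#' @param idx integer vector of feature indices in 1..R(R-1)/2.
#' @param R region count (>= 3).
#' @return `pairOfIndex()`: integer matrix with columns `i`, `j`, one row per
#'   index.  `indexOfPair()`: integer vector of feature indices.
#' @examples
#' pairOfIndex(1, 90)      # pair (1, 2)
#' pairOfIndex(4005, 90)   # pair (89, 90)
#' indexOfPair(89, 90, 90) # 4005
#' @export
pairOfIndex <- function(idx, R) {
  R <- as.integer(R)
  if (R < 3L) stop("`R` must be at least 3")
  P <- (R * (R - 1L)) %/% 2L
  idx <- as.integer(idx)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > P))
    stop("feature index out of range 1..", P)
  k <- idx - 1L
  # largest i0 (0-based) whose row offset i0*R - i0*(i0+1)/2 <= k
  i0 <- floor(((2 * R - 1) - sqrt((2 * R - 1)^2 - 8 * k)) / 2)
  i0 <- as.integer(i0)
  # guard floating-point edges
  offset <- i0 * R - (i0 * (i0 + 1L)) %/% 2L
  fix <- offset > k
  i0[fix] <- i0[fix] - 1L
  offset <- i0 * R - (i0 * (i0 + 1L)) %/% 2L
  j0 <- k - offset + i0 + 1L
  cbind(i = i0 + 1L, j = as.integer(j0) + 1L)
}

#' @rdname pairOfIndex
#' @param i,j region indices with `i < j`, both in 1..R.
#' @export
indexOfPair <- function(i, j, R) {
  R <- as.integer(R)
  i <- as.integer(i); j <- as.integer(j)
  if (any(i < 1L) || any(j <= i) || any(j > R))
    stop("need 1 <= i < j <= R")
  i0 <- i - 1L; j0 <- j - 1L
  as.integer(i0 * R - (i0 * (i0 + 1L)) %/% 2L + (j0 - i0 - 1L) + 1L)
}

#' Head-motion quality control
#'
#' Flags subjects for exclusion when their maximum absolute translation
#' exceeds `trans_limit` millimetres or their maximum absolute rotation
#' exceeds `rot_limit` degrees.  The comparison is strict: a subject exactly
#' at a limit is kept.
#'
#' @param max_abs_translation_mm,max_abs_rotation_deg non-negative numeric
#'   vectors of per-subject motion summaries.
#' @param trans_limit translation limit in mm (default 2).
#' @param rot_limit rotation limit in degrees (default 2).
#' @return Logical vector: `TRUE` = include, `FALSE` = exclude.
#' @export
motionQC <- function(max_abs_translation_mm, max_abs_rotation_deg,
                     trans_limit = 2.0, rot_limit = 2.0) {
  tr <- as.numeric(max_abs_translation_mm)
  ro <- as.numeric(max_abs_rotation_deg)
  if (length(tr) != length(ro)) stop("motion summaries must have equal length")
  if (any(!is.finite(tr)) || any(!is.finite(ro)) || any(tr < 0) || any(ro < 0))
    stop("motion summaries must be finite and non-negative")
  !(tr > trans_limit | ro > rot_limit)
}

#' Packaged AAL-90 region table
#'
#' The 90 cerebral regions of the Automatic Anatomical Labeling atlas
#' (45 per hemisphere; odd indices left, even right), with the standard
#' abbreviations (e.g. `ORBinf.L`) and full names.
#'
#' @return data.frame with columns `index`, `abbreviation`, `full_name`,
#'   `hemisphere`.
#' @export
aal90Regions <- function() {
  f <- system.file("extdata", "aal90_regions.csv", package = "rsvmcluster",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Build a subjects-by-features connectivity dataset
#'
#' Applies [pearsonMatrix()] and [vectorizeUpper()] to every subject and
#' stacks the resulting connectivity vectors into an N x R(R-1)/2 feature
#' matrix.
#'
#' @param subjects list of [roiTimeSeries()] objects (or a `syntheticCohort`,
#'   whose labels are then used automatically).
#' @param labels factor (or coercible) of length N with exactly two levels.
#'   The first level is treated as the positive (patient) class.
#' @return An [fcDataset()] object.
#' @export
connectivityFeatures <- function(subjects, labels = NULL) {
  if (inherits(subjects, "syntheticCohort")) {
    labels <- labels %||% subjects$labels
    subjects <- subjects$subjects
  }
  if (is.null(labels)) stop("`labels` required when `subjects` is a plain list")
  feats <- t(vapply(subjects,
                    function(s) vectorizeUpper(pearsonMatrix(s)),
                    numeric(ncol(subjects[[1L]]$data) *
                            (ncol(subjects[[1L]]$data) - 1L) / 2L)))
  rownames(feats) <- vapply(subjects, function(s) s$subject_id, character(1L))
  fcDataset(feats, labels, subject_ids = rownames(feats))
}

#' Read one subject's ROI time series from a delimited text file
#'
#' Expects a CSV with one column per region (header row = region labels) and
#' one row per time point.
#'
#' @param file path to the CSV file.
#' @param subject_id subject identifier; defaults to the file name.
#' @return An [roiTimeSeries()] object.
#' @export
readRoiTimeSeries <- function(file, subject_id = NULL) {
  subject_id <- subject_id %||% sub("\\.[^.]*$", "", basename(file))
  df <- utils::read.csv(file, check.names = FALSE)
  roiTimeSeries(as.matrix(df), subject_id = subject_id,
                region_labels = colnames(df))
}
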
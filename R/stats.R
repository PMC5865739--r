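#' Pearson chi-square test for a 2x2 contingency table
#'
#' Pearson's chi-square on a 2x2 table of counts with 1 degree of freedom
#' and *no* continuity correction — the form conventionally used for
#' gender-by-group comparisons in cohort description tables.
#'
#' @param a,b first row of counts (group 1: e.g. males, females).
#' @param c,d second row of counts (group 2).  Alternatively pass a 2x2
#'   matrix as `a`.
#' @return list with `statistic`, `df` (= 1) and `p_value`.
#' @examples
#' chiSquare2x2(12, 13, 15, 20)  # p = 0.693
#' @export
chiSquare2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2L, 2L)
  if (!all(dim(m) == 2L)) stop("need a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("every row and column total must be positive")
  ct <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ct$statistic), df = 1L,
       p_value = unname(ct$p.value))
}

#' Pooled two-sample t test from summary statistics
#'
#' Student's two-sample t test with pooled variance, computed from group
#' means, standard deviations and sizes (as printed in a cohort description
#' table), with `n1 + n2 - 2` degrees of freedom and a two-sided p-value.
#'
#' @param mean1,sd1,n1 first group's mean, SD (> 0) and size (>= 2).
#' @param mean2,sd2,n2 second group's summaries.
#' @return list with `t`, `df` and `p_value`.
#' @examples
#' tTestFromSummary(74.59, 7.03, 25, 77.09, 6.69, 35)  # p = 0.168
#' @export
tTestFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}
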
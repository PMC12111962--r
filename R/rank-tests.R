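#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()] fixing the conventions used
#' throughout the package: exact enumeration when the combined sample size is
#' at most 20 and the data carry no ties, otherwise the normal approximation
#' with tie correction and continuity correction. When every value in both
#' samples is identical the tie-corrected variance vanishes; that degenerate
#' case is defined to have p = 1 (no evidence of a shift).
#'
#' @param x,y numeric samples from the two cohorts.
#' @return the two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  z <- c(x, y)
  if (max(z) == min(z)) return(1)
  use_exact <- (length(z) <= 20L) && !anyDuplicated(z)
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  unname(min(1, res$p.value))
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for a family of `m` tests.
#'
#' @param p raw p-value(s).
#' @param m_tests family size (defaults to `length(p)`).
#' @return adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p, m_tests = length(p)) {
  assert_count(m_tests, "m_tests")
  pmin(1, m_tests * p)
}

#' Empirical p-value with add-one correction
#'
#' `(1 + #\{null >= observed\}) / (B + 1)`; never zero, so B = 50,000 with no
#' exceedance reports p = 1/50,001 (i.e. "p < 2e-5").
#'
#' @param observed observed statistic.
#' @param null vector of resampled null statistics.
#' @return the empirical p-value.
#' @export
empirical_pvalue <- function(observed, null) {
  stopifnot(length(observed) == 1L, length(null) >= 1L)
  (1 + sum(null >= observed)) / (length(null) + 1)
}
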
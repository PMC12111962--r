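#' Two-sided Fisher exact test for a 2x2 table of cohort counts
#'
#' The single exact-test routine shared by the carrier-rate comparison, the
#' signature-presence comparison and the per-gene frequency comparison.
#' Conditioning on both margins, the count in cohort 1 follows a
#' hypergeometric distribution; the two-sided p-value is the probability-mass
#' rule used by mainstream exact-test implementations: the sum of the
#' probabilities of all tables with fixed margins whose probability does not
#' exceed that of the observed table, with a relative tolerance of 1e-7 on
#' the comparison to absorb floating-point noise.
#'
#' @param k1,n1 successes and size in cohort 1 (e.g. carriers / patients).
#' @param k2,n2 successes and size in cohort 2.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact(8, 25, 16, 250)   # carrier-rate style comparison
#' @export
fisher_exact <- function(k1, n1, k2, n2) {
  stopifnot(length(k1) == 1L, length(n1) == 1L, length(k2) == 1L,
            length(n2) == 1L)
  if (any(c(k1, n1, k2, n2) < 0) || k1 > n1 || k2 > n2)
    stop("counts must satisfy 0 <= k <= n in both cohorts", call. = FALSE)
  if (n1 + n2 == 0)
    stop("degenerate margins: both cohorts are empty", call. = FALSE)
  K <- k1 + k2
  support <- max(0, K - n2):min(n1, K)
  d <- dhyper(support, n1, n2, K)
  d_obs <- dhyper(k1, n1, n2, K)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' Vectorized two-sided Fisher exact test
#'
#' Applies [fisher_exact()] element-wise; used for per-gene tables.
#'
#' @param k1,n1,k2,n2 equal-length vectors of counts.
#' @return a vector of two-sided p-values.
#' @export
fisher_exact_many <- function(k1, n1, k2, n2) {
  n <- length(k1)
  stopifnot(length(n1) == n, length(k2) == n, length(n2) == n)
  vapply(seq_len(n), function(i) fisher_exact(k1[i], n1[i], k2[i], n2[i]),
         numeric(1))
}
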
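#' Refit per-patient signature exposures by non-negative least squares
#'
#' For each patient with 96-channel counts m, solves
#' \deqn{\min_e \| m - S e \|_2 \quad \mathrm{s.t.}\ e \ge 0}
#' where S is the signature catalog, via the Lawson-Hanson active-set
#' algorithm ([pracma::lsqnonneg()]). Exposures are attributed mutation
#' counts; proportions are exposures normalized per patient. Refitting is
#' plain per-patient NNLS by design: it is deterministic and sufficient for
#' the cohort-level contrasts downstream, and deliberately omits the
#' forward-selection sparsity heuristics of published assignment tools.
#'
#' Patients with an all-zero catalog row get zero exposures and undefined
#' (NA) proportions, and are flagged in `defined`.
#'
#' @param catalog patient x 96 count matrix (see [build_catalog()]).
#' @param sigs 96 x K signature catalog; rownames must match the channel set.
#' @return an object of class `exposure_table`: list with `exposures`
#'   (patients x K), `proportions` (patients x K, rows sum to 1 where
#'   defined), and `defined` (logical per patient).
#' @export
refit_exposures <- function(catalog, sigs) {
  sigs <- validate_signature_catalog(sigs)
  if (ncol(catalog) != 96L || !setequal(colnames(catalog), sbs96_channels()))
    stop("catalog must have the 96 SBS channels as columns", call. = FALSE)
  catalog <- catalog[, rownames(sigs), drop = FALSE]
  n <- nrow(catalog); K <- ncol(sigs)
  exposures <- matrix(0, n, K, dimnames = list(rownames(catalog), colnames(sigs)))
  for (i in seq_len(n)) {
    m <- as.numeric(catalog[i, ])
    if (sum(m) > 0) exposures[i, ] <- pracma::lsqnonneg(sigs, m)$x
  }
  totals <- rowSums(exposures)
  defined <- totals > 0
  proportions <- exposures / ifelse(totals > 0, totals, NA_real_)
  structure(list(exposures = exposures, proportions = proportions,
                 defined = defined),
            class = "exposure_table")
}

#' @export
print.exposure_table <- function(x, ...) {
  cat("exposure_table:", nrow(x$exposures), "patients x",
      ncol(x$exposures), "signatures;", sum(x$defined), "with defined proportions\n")
  invisible(x)
}

#' Cohort signature summary: mean of individual proportions
#'
#' Averages each signature's per-patient proportion over the patients with
#' defined proportions. Working on proportions rather than raw attributed
#' counts keeps patients with very different mutation burdens on an equal
#' footing, so the summary is not dominated by hypermutated samples.
#'
#' @param exposures an `exposure_table`.
#' @return named numeric vector of per-signature means, summing to 1.
#' @export
cohort_signature_summary <- function(exposures) {
  stopifnot(inherits(exposures, "exposure_table"))
  if (!any(exposures$defined))
    stop("no patient has defined proportions", call. = FALSE)
  colMeans(exposures$proportions[exposures$defined, , drop = FALSE])
}

#' Compare one signature's per-patient proportions between two cohorts
#'
#' Two-sided Wilcoxon-Mann-Whitney on the per-patient proportions, with
#' Bonferroni adjustment over the family of signatures tested.
#'
#' @param propsA,propsB per-patient proportions of one signature in each
#'   cohort (patients with undefined proportions already removed).
#' @param m_tests Bonferroni family size; defaults to 1 (report the raw p).
#' @return list with `p_raw` and `p_adjusted`.
#' @export
compare_signature_between_cohorts <- function(propsA, propsB, m_tests = 1) {
  p <- rank_sum_test(propsA, propsB)
  list(p_raw = p, p_adjusted = unname(bonferroni_adjust(p, m_tests)))
}

#' Per-signature presence counts in a cohort
#'
#' A signature is "present" in a patient when its attributed proportion
#' exceeds `presence_epsilon`. The default 0 counts any positive attribution
#' as presence; NNLS already returns exact zeros for signatures it does not
#' use, so the default is not vacuous. Patients with undefined proportions
#' are excluded from both numerator and denominator.
#'
#' @param exposures an `exposure_table`.
#' @param presence_epsilon presence threshold on the proportion scale.
#' @return list with `present` (named counts per signature) and `n` patients.
#' @export
signature_presence <- function(exposures, presence_epsilon = 0) {
  stopifnot(inherits(exposures, "exposure_table"))
  assert_fraction(presence_epsilon, "presence_epsilon")
  pr <- exposures$proportions[exposures$defined, , drop = FALSE]
  list(present = colSums(pr > presence_epsilon), n = nrow(pr))
}

#' Compare a signature's presence frequency between two cohorts
#'
#' Delegates to the shared two-sided Fisher exact routine, e.g. to ask
#' whether the tobacco signature is present in fewer smokers in one cohort
#' than in the other.
#'
#' @param presentA,nA patients with the signature / total in cohort A.
#' @param presentB,nB the same for cohort B.
#' @return two-sided Fisher p-value.
#' @export
signature_presence_test <- function(presentA, nA, presentB, nB) {
  fisher_exact(presentA, nA, presentB, nB)
}
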
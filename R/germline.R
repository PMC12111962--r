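## Germline variant prioritization cascade and carrier-rate comparison.

GERMLINE_VOCAB <- c("Pathogenic", "Likely pathogenic",
                    "Uncertain significance", "other")
PLP <- c("Pathogenic", "Likely pathogenic")

#' Classify annotated germline variants through the prioritization cascade
#'
#' A variant is retained as P/LP when it (1) is reported Pathogenic or
#' Likely pathogenic, (2) has maximum population allele frequency strictly
#' below `af_threshold` in every population reported, (3) lies in a cancer
#' susceptibility gene from `genes`, and (4) passed manual review
#' (`review_pass`, a flag standing in for IGV inspection). A variant of
#' Uncertain significance is rescued under the same AF/gene/review
#' conditions when at least two of three in-silico criteria hold: CADD phred
#' above 20, PolyPhen "Probably damaging" or "Possibly damaging", SIFT
#' "Deleterious". Missing predictor values count as not met, never as met.
#'
#' Every variant receives exactly one decision; excluded variants carry the
#' first failing criterion, checked in cascade order: `vocabulary`
#' (unknown clinical-significance label), `significance`, `af`,
#' `gene_list`, `review`, `insufficient_predictors`.
#'
#' @param variants data frame with columns `patient_id`, `gene`,
#'   `clinical_significance`, `cadd_phred`, `polyphen`, `sift`,
#'   `review_pass`, plus one or more population allele-frequency columns
#'   prefixed `af_` (e.g. `af_gnomad`, `af_1000g`); NA means not reported.
#' @param genes character vector of susceptibility gene symbols.
#' @param af_threshold strict upper bound on the maximum population AF;
#'   default 0.05.
#' @return `variants` with added columns `decision`
#'   (`retained_PLP` / `retained_VUS` / `excluded`) and `reason`
#'   (`NA` for retained variants).
#' @export
classify_variants <- function(variants, genes, af_threshold = 0.05) {
  assert_fraction(af_threshold, "af_threshold")
  if (af_threshold == 0) stop("af_threshold must be in (0, 1]", call. = FALSE)
  if (length(genes) == 0) stop("empty susceptibility gene list", call. = FALSE)
  need <- c("patient_id", "gene", "clinical_significance", "cadd_phred",
            "polyphen", "sift", "review_pass")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("germline table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  af_cols <- grep("^af_", names(variants), value = TRUE)
  if (length(af_cols) == 0)
    stop("germline table needs at least one 'af_*' population AF column",
         call. = FALSE)
  af <- as.matrix(variants[af_cols])
  if (any(af < 0 | af > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  ## absent from every frequency database => treated as rare (passes AF)
  max_af <- suppressWarnings(apply(af, 1, max, na.rm = TRUE))
  max_af[!is.finite(max_af)] <- 0

  sig <- as.character(variants$clinical_significance)
  n <- nrow(variants)
  decision <- rep("excluded", n)
  reason <- rep(NA_character_, n)

  bad_vocab <- !(sig %in% GERMLINE_VOCAB)
  if (any(bad_vocab))
    message(sum(bad_vocab),
            " variant(s) with unrecognized clinical-significance label excluded")
  predictors <- cbind(
    cadd = !is.na(variants$cadd_phred) & variants$cadd_phred > 20,
    polyphen = !is.na(variants$polyphen) &
      variants$polyphen %in% c("Probably damaging", "Possibly damaging"),
    sift = !is.na(variants$sift) & variants$sift == "Deleterious")
  n_pred <- rowSums(predictors)
  review <- !is.na(variants$review_pass) & variants$review_pass

  for (i in seq_len(n)) {
    if (bad_vocab[i]) { reason[i] <- "vocabulary"; next }
    if (!(sig[i] %in% c(PLP, "Uncertain significance"))) {
      reason[i] <- "significance"; next
    }
    if (max_af[i] >= af_threshold) { reason[i] <- "af"; next }
    if (!(variants$gene[i] %in% genes)) { reason[i] <- "gene_list"; next }
    if (!review[i]) { reason[i] <- "review"; next }
    if (sig[i] %in% PLP) {
      decision[i] <- "retained_PLP"
    } else if (n_pred[i] >= 2) {
      decision[i] <- "retained_VUS"
    } else {
      reason[i] <- "insufficient_predictors"
    }
  }
  variants$decision <- decision
  variants$reason <- reason
  variants
}

#' Per-patient carrier status from classified variants
#'
#' A patient is a carrier iff at least one of their variants was retained
#' (P/LP or rescued VUS).
#'
#' @param classified output of [classify_variants()].
#' @param patient_ids full cohort patient ids (patients without any variant
#'   record are non-carriers).
#' @return data frame with `patient_id` and logical `carrier`.
#' @export
carrier_table <- function(classified, patient_ids) {
  retained <- classified[startsWith(classified$decision, "retained"), ,
                         drop = FALSE]
  data.frame(patient_id = patient_ids,
             carrier = patient_ids %in% retained$patient_id,
             stringsAsFactors = FALSE)
}

#' Fraction of patients carrying a retained germline variant
#'
#' @param carriers number of carriers (or a [carrier_table()] data frame).
#' @param n_patients cohort size.
#' @return carriers / n_patients.
#' @export
carrier_proportion <- function(carriers, n_patients) {
  if (is.data.frame(carriers)) carriers <- sum(carriers$carrier)
  assert_count(n_patients, "n_patients")
  assert_count(carriers, "carriers", positive = FALSE)
  if (carriers > n_patients)
    stop("more carriers than patients", call. = FALSE)
  carriers / n_patients
}

#' Compare carrier rates between two cohorts
#'
#' Two-sided Fisher exact test on the 2x2 carrier table, via the shared
#' exact routine.
#'
#' @param k1,n1 carriers and size of cohort 1.
#' @param k2,n2 carriers and size of cohort 2.
#' @return two-sided p-value.
#' @export
compare_carrier_rates <- function(k1, n1, k2, n2) {
  fisher_exact(k1, n1, k2, n2)
}
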
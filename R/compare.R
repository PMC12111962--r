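## Per-gene somatic frequency comparisons and tumor mutational burden.

#' Per-gene mutated-patient fractions
#'
#' A patient counts once per gene no matter how many qualifying mutations
#' they carry there. Silent mutations are excluded by default, matching the
#' usual driver-frequency convention; pass `include_silent = TRUE` to count
#' them.
#'
#' @param somatic mutation table (`patient_id`, `gene`, `variant_class`).
#' @param n_patients cohort size (denominator; may exceed the number of
#'   mutated patients).
#' @param include_silent count silent mutations too? Default `FALSE`.
#' @return data frame with `gene`, `mutated` (distinct patients), `total`
#'   and `frequency`, sorted by decreasing frequency then symbol.
#' @export
gene_frequency_table <- function(somatic, n_patients, include_silent = FALSE) {
  assert_count(n_patients, "n_patients")
  keep <- if (include_silent) rep(TRUE, nrow(somatic))
          else somatic$variant_class != "silent"
  pairs <- unique(somatic[keep, c("patient_id", "gene")])
  counts <- table(pairs$gene)
  if (any(counts > n_patients))
    stop("more mutated patients than n_patients for some gene", call. = FALSE)
  out <- data.frame(gene = names(counts), mutated = as.integer(counts),
                    total = n_patients,
                    frequency = as.integer(counts) / n_patients,
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$gene), , drop = FALSE]
}

#' Compare per-gene mutation frequencies between two cohorts
#'
#' Two-sided Fisher exact test per gene on the mutated/unmutated 2x2 table,
#' via the shared exact routine, with optional Bonferroni correction over
#' the genes tested. A gene observed in only one cohort is compared against
#' 0 mutated patients out of that cohort's total, with a warning.
#'
#' @param countsA,countsB data frames with `gene`, `mutated`, `total`
#'   (as produced by [gene_frequency_table()]).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return data frame with per-gene counts in both cohorts, `frequencyA`,
#'   `frequencyB`, `freq_difference`, `p`, `p_adjusted`.
#' @export
compare_gene_frequencies <- function(countsA, countsB,
                                     correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  for (tb in list(countsA, countsB))
    if (!all(c("gene", "mutated", "total") %in% names(tb)))
      stop("count tables need columns gene, mutated, total", call. = FALSE)
  totalA <- max(countsA$total, 0)
  totalB <- max(countsB$total, 0)
  only <- c(setdiff(countsA$gene, countsB$gene),
            setdiff(countsB$gene, countsA$gene))
  if (length(only))
    warning(length(only),
            " gene(s) present in one cohort only; compared against 0/total")
  genes <- sort(union(countsA$gene, countsB$gene))
  ka <- setNames(rep(0L, length(genes)), genes)
  ka[countsA$gene] <- countsA$mutated
  kb <- setNames(rep(0L, length(genes)), genes)
  kb[countsB$gene] <- countsB$mutated
  p <- fisher_exact_many(ka, rep(totalA, length(genes)),
                         kb, rep(totalB, length(genes)))
  p_adj <- if (correction == "bonferroni") bonferroni_adjust(p) else p
  data.frame(gene = genes,
             mutatedA = as.integer(ka), totalA = totalA,
             mutatedB = as.integer(kb), totalB = totalB,
             frequencyA = ka / totalA, frequencyB = kb / totalB,
             freq_difference = ka / totalA - kb / totalB,
             p = p, p_adjusted = p_adj,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tumor mutational burden per patient
#'
#' Counts non-synonymous mutations (splice site, missense, nonsense,
#' nonstop) per patient and divides by the capture size in megabases
#' (default 37.5 Mb, a common whole-exome library size).
#'
#' @param somatic mutation table (`patient_id`, `variant_class`).
#' @param capture_mb exome capture size in Mb; default 37.5.
#' @param patients optional full patient id vector so patients with no
#'   qualifying mutation appear with TMB 0.
#' @return list with `per_patient` (data frame `patient_id`, `n_nonsyn`,
#'   `capture_mb`, `tmb`) and `median_tmb`.
#' @export
compute_tmb <- function(somatic, capture_mb = 37.5, patients = NULL) {
  if (!is.numeric(capture_mb) || capture_mb <= 0)
    stop("capture_mb must be positive", call. = FALSE)
  if (is.null(patients))
    patients <- sort(unique(as.character(somatic$patient_id)))
  keep <- somatic$variant_class %in% nonsyn_classes()
  counts <- table(factor(as.character(somatic$patient_id)[keep],
                         levels = patients))
  per <- data.frame(patient_id = patients,
                    n_nonsyn = as.integer(counts),
                    capture_mb = capture_mb,
                    tmb = as.integer(counts) / capture_mb,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(per_patient = per, median_tmb = median(per$tmb))
}
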
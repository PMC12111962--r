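## Driver-gene consensus: decile extraction, joint detection, bootstrap
## nulls for multi-tool coincidence and cross-cohort overlap, a Poisson
## recurrence stand-in ranker, and the subsample sample-size bias test.

#' Build a ranking table from per-gene scores
#'
#' Ranks genes by score with deterministic tie-breaking: ties are resolved
#' by lexicographically smaller gene symbol. Rank 1 is the strongest driver
#' candidate.
#'
#' @param tool label for the scoring tool.
#' @param gene gene symbols (unique).
#' @param score per-gene scores.
#' @param higher_is_better if `TRUE` larger scores rank first (latent driver
#'   scores); if `FALSE` smaller rank first (p-value-like scores).
#' @return data frame with columns `tool`, `gene`, `score`, `rank`.
#' @export
ranking_table <- function(tool, gene, score, higher_is_better = TRUE) {
  stopifnot(length(gene) == length(score), !anyDuplicated(gene))
  if (length(gene) == 0) stop("empty ranking table", call. = FALSE)
  o <- order(if (higher_is_better) -score else score, gene)
  rank <- integer(length(gene)); rank[o] <- seq_along(gene)
  data.frame(tool = tool, gene = as.character(gene), score = score,
             rank = rank, stringsAsFactors = FALSE)
}

validate_ranking <- function(r) {
  need <- c("tool", "gene", "score", "rank")
  miss <- setdiff(need, names(r))
  if (length(miss))
    stop("ranking table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(r$gene))
    stop("ranking table has duplicated gene symbols", call. = FALSE)
  if (!setequal(r$rank, seq_len(nrow(r))))
    stop("ranks must be a permutation of 1..G", call. = FALSE)
  invisible(r)
}

#' Extract the top decile (or other fraction) of a ranking table
#'
#' Returns the `ceiling(fraction * G)` best-ranked genes.
#'
#' @param r ranking table (see [ranking_table()]).
#' @param fraction fraction of genes to keep, default 0.10.
#' @return character vector of gene symbols.
#' @export
top_decile <- function(r, fraction = 0.10) {
  validate_ranking(r)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  k <- ceiling(fraction * nrow(r))
  r$gene[order(r$rank)][seq_len(k)]
}

#' Genes jointly detected by at least `min_tools` gene sets
#'
#' @param sets list of gene-symbol vectors (e.g. top deciles per tool).
#' @param min_tools minimum number of sets a gene must appear in; default 2.
#' @return sorted character vector.
#' @export
joint_detection <- function(sets, min_tools = 2) {
  assert_count(min_tools, "min_tools")
  if (min_tools > length(sets))
    stop("min_tools exceeds the number of sets", call. = FALSE)
  tab <- table(unlist(lapply(sets, unique)))
  sort(names(tab)[tab >= min_tools])
}

#' Bootstrap test for multi-tool coincidence in gene rankings
#'
#' Asks whether the top deciles of several ranking tools coincide more than
#' chance allows. The statistic is the size of the joint set (genes in the
#' top decile of at least `min_tools` tools). The null draws, for each of B
#' resamples, independent uniform random gene sets of the same sizes from
#' the shared universe and recomputes the statistic; the empirical p-value
#' uses the add-one convention, so p is never 0 and
#' p = 1/(B+1) indicates no null resample reached the observed value.
#'
#' The universe is the set of genes scored by at least `min_tools` of the
#' tables, so a gene that could never enter the joint set does not inflate
#' the null.
#'
#' @param rankings list of ranking tables (typically three).
#' @param fraction decile fraction, default 0.10.
#' @param min_tools joint-detection threshold, default 2.
#' @param B number of resamples, default 50000.
#' @param seed integer seed for the null draws.
#' @return object of class `consensus_result`: list with `decile_sets`,
#'   `joint_set`, `observed_stat`, `null_stats`, `p_empirical`, `B`, `seed`,
#'   `universe`.
#' @export
multi_tool_coincidence_test <- function(rankings, fraction = 0.10,
                                        min_tools = 2, B = 50000, seed = 1) {
  stopifnot(is.list(rankings), length(rankings) >= 2)
  lapply(rankings, validate_ranking)
  assert_count(B, "B")
  gene_sets <- lapply(rankings, function(r) r$gene)
  universe <- joint_detection(gene_sets, min_tools)
  if (length(universe) == 0)
    stop("no gene is scored by at least min_tools tables", call. = FALSE)
  deciles <- lapply(rankings, top_decile, fraction = fraction)
  joint <- joint_detection(deciles, min_tools)
  observed <- length(joint)
  sizes <- vapply(deciles, function(d) length(intersect(d, universe)),
                  integer(1))
  U <- length(universe)
  sizes <- pmin(sizes, U)
  set.seed(seed)
  null_stats <- integer(B)
  for (b in seq_len(B)) {
    hits <- tabulate(unlist(lapply(sizes, function(s) sample.int(U, s))), U)
    null_stats[b] <- sum(hits >= min_tools)
  }
  structure(list(decile_sets = deciles, joint_set = joint,
                 observed_stat = observed, null_stats = null_stats,
                 p_empirical = empirical_pvalue(observed, null_stats),
                 B = B, seed = seed, universe = universe),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result: joint set", x$observed_stat, "genes of",
      length(x$universe), "; empirical p =", format(x$p_empirical), " (B =",
      x$B, ")\n")
  invisible(x)
}

#' Bootstrap test for cross-cohort overlap of gene sets
#'
#' Null: draw random subsets of the universe with the sizes of `setA` and
#' `setB` and record their intersection size, B times; the empirical p-value
#' is the add-one fraction of resamples with intersection at least the
#' observed. Also reports the analytic expectation |A||B|/|U| of the null
#' intersection.
#'
#' @param setA,setB gene sets (character), both subsets of `universe`.
#' @param universe gene universe (character, unique).
#' @param B number of resamples, default 50000.
#' @param seed integer seed.
#' @return object of class `overlap_test_result`: list with
#'   `observed_overlap`, `null_stats`, `p_empirical`, `expected_null`, `B`,
#'   `seed`, and the input sizes.
#' @export
cross_cohort_overlap_test <- function(setA, setB, universe, B = 50000,
                                      seed = 1) {
  universe <- unique(as.character(universe))
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("setA and setB must be subsets of the universe", call. = FALSE)
  assert_count(B, "B")
  a <- length(setA); b <- length(setB); U <- length(universe)
  observed <- length(intersect(setA, setB))
  set.seed(seed)
  null_stats <- integer(B)
  for (k in seq_len(B)) {
    ia <- sample.int(U, a)
    ib <- sample.int(U, b)
    null_stats[k] <- sum(tabulate(c(ia, ib), U) == 2L)
  }
  structure(list(observed_overlap = observed, null_stats = null_stats,
                 p_empirical = empirical_pvalue(observed, null_stats),
                 expected_null = a * b / U,
                 size_a = a, size_b = b, size_universe = U,
                 B = B, seed = seed),
            class = "overlap_test_result")
}

#' @export
print.overlap_test_result <- function(x, ...) {
  cat("overlap_test_result:", x$observed_overlap, "of |A| =", x$size_a,
      ", |B| =", x$size_b, "in |U| =", x$size_universe,
      "; expected", format(x$expected_null), "; empirical p =",
      format(x$p_empirical), "\n")
  invisible(x)
}

#' Poisson recurrence ranker
#'
#' A simple, transparent stand-in for external positive-selection tools,
#' used by the subsample bias test and as a pluggable default ranker. Each
#' gene's score is the upper-tail Poisson probability of observing at least
#' its non-synonymous mutation count, under a neutral expectation
#' proportional to its coding length (cohort-wide non-synonymous rate per
#' base times gene length). Smaller scores rank first; ties break
#' lexicographically.
#'
#' @param somatic mutation table with `gene` and `variant_class` columns.
#' @param gene_lengths named numeric vector of per-gene coding lengths in
#'   bases; defines the gene universe.
#' @param tool tool label, default `"recurrence"`.
#' @return ranking table over `names(gene_lengths)`.
#' @export
recurrence_ranker <- function(somatic, gene_lengths, tool = "recurrence") {
  if (is.null(names(gene_lengths)) || any(gene_lengths <= 0))
    stop("gene_lengths must be a named vector of positive lengths",
         call. = FALSE)
  genes <- names(gene_lengths)
  keep <- somatic$variant_class %in% nonsyn_classes()
  mutated <- somatic$gene[keep]
  missing <- setdiff(unique(mutated), genes)
  if (length(missing))
    stop("mutated gene(s) missing a length: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  counts <- table(factor(mutated, levels = genes))
  rate <- sum(counts) / sum(gene_lengths)
  lambda <- rate * gene_lengths
  score <- ppois(as.numeric(counts) - 1, lambda, lower.tail = FALSE)
  ranking_table(tool, genes, score, higher_is_better = FALSE)
}

#' Subsample bootstrap for sample-size bias in top-decile calls
#'
#' Repeatedly draws `m` patients without replacement from a large reference
#' cohort, re-runs the ranker on their mutations, takes the top decile, and
#' records (i) its intersection size with a reference driver list and (ii)
#' the fraction of its genes outside that list. The resulting null
#' distribution shows how much of a small cohort's apparent novelty is
#' explained by sample size alone; an observed non-reference fraction from a
#' query cohort can be placed on it as a quantile.
#'
#' @param somatic reference cohort mutation table (`patient_id`, `gene`,
#'   `variant_class`).
#' @param reference_drivers reference driver gene list (character).
#' @param gene_lengths named vector of gene lengths for the ranker.
#' @param m subsample size, default 25.
#' @param B number of subsamples.
#' @param fraction decile fraction, default 0.10.
#' @param ranker function `(somatic, gene_lengths) -> ranking table`;
#'   default [recurrence_ranker()].
#' @param seed integer seed.
#' @param observed_nonref optional observed non-reference fraction from a
#'   query cohort, placed on the null as a quantile.
#' @return object of class `subsample_bias_result`: list with
#'   `intersections`, `proportion_nonreference` (both length B), `m`, `B`,
#'   `seed`, and when `observed_nonref` is given, `observed_nonref` and
#'   `observed_quantile` (fraction of null values below it).
#' @export
subsample_bias_test <- function(somatic, reference_drivers, gene_lengths,
                                m = 25, B = 200, fraction = 0.10,
                                ranker = recurrence_ranker, seed = 1,
                                observed_nonref = NULL) {
  patients <- unique(as.character(somatic$patient_id))
  assert_count(m, "m"); assert_count(B, "B")
  if (m >= length(patients))
    stop("m must be smaller than the reference cohort size", call. = FALSE)
  set.seed(seed)
  inter <- integer(B); nonref <- numeric(B)
  for (b in seq_len(B)) {
    ids <- sample(patients, m)
    sub <- somatic[somatic$patient_id %in% ids, , drop = FALSE]
    dec <- top_decile(ranker(sub, gene_lengths), fraction)
    inter[b] <- length(intersect(dec, reference_drivers))
    nonref[b] <- 1 - inter[b] / length(dec)
  }
  out <- list(intersections = inter, proportion_nonreference = nonref,
              m = m, B = B, seed = seed)
  if (!is.null(observed_nonref)) {
    out$observed_nonref <- observed_nonref
    out$observed_quantile <- mean(nonref < observed_nonref)
  }
  structure(out, class = "subsample_bias_result")
}

#' @export
print.subsample_bias_result <- function(x, ...) {
  cat("subsample_bias_result: m =", x$m, ", B =", x$B,
      "; mean intersection", format(mean(x$intersections)),
      "; mean non-reference fraction",
      format(mean(x$proportion_nonreference)), "\n")
  invisible(x)
}
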
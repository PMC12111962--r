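## Synthetic cohorts with planted ground truth: signature mixtures, driver
## genes, germline carriers, and ranking tables with tunable concordance.

#' Simulation configuration
#'
#' Defaults emulate the kind of small whole-exome tumor cohort the pipeline
#' targets: 25 patients, roughly 900 somatic SNVs per patient, about 8%
#' indels, 32% germline carriers, and a smoking mix with an "unknown" level
#' reflecting incomplete clinical records. Drivers are planted by
#' multiplying selected genes' mutation rates.
#'
#' @param n_patients number of patients; default 25.
#' @param n_genes number of genes; default 1000.
#' @param gene_lengths optional named vector of per-gene coding lengths in
#'   bases; drawn from a gamma distribution (mean ~1700 bp) when `NULL`.
#' @param mutation_rate expected somatic mutations per patient; default 900.
#' @param driver_genes symbols (or a count, taken from the head of the gene
#'   list) of planted driver genes; default none.
#' @param driver_multiplier per-base rate multiplier for planted drivers
#'   (>= 1); default 10.
#' @param signature_mixture Dirichlet concentration vector over the K
#'   catalog signatures; default `rep(1, K)` at generation time. A zero
#'   concentration is allowed as the degenerate limit and pins that
#'   signature's planted exposure to exactly 0.
#' @param carrier_rate fraction of patients planted with one qualifying
#'   germline variant; default 0.32.
#' @param decoy_rate fraction of non-carriers receiving a decoy germline
#'   variant that fails exactly one filter criterion; default 0.5.
#' @param susceptibility_genes symbols (or a count) forming the cancer
#'   susceptibility gene list; default `min(152, n_genes)` genes from the
#'   tail of the gene list (disjoint from default drivers).
#' @param ranking_concordance scalar in `[0, 1]`: 1 gives identical tool
#'   orders, 0 independent random orders; default 0.8.
#' @param driver_rank_boost additive boost of planted drivers' shared latent
#'   score, in standard deviations; default 5.
#' @param smoking_probs probabilities for ever/never/unknown smoking status.
#' @param class_probs probabilities over variant classes (missense, silent,
#'   nonsense, splice_site, nonstop, indel).
#' @param seed master seed; all stage seeds derive from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 25, n_genes = 1000, gene_lengths = NULL,
                       mutation_rate = 900, driver_genes = character(0),
                       driver_multiplier = 10, signature_mixture = NULL,
                       carrier_rate = 0.32, decoy_rate = 0.5,
                       susceptibility_genes = NULL,
                       ranking_concordance = 0.8, driver_rank_boost = 5,
                       smoking_probs = c(ever = 0.40, never = 0.28,
                                         unknown = 0.32),
                       class_probs = c(missense = 0.62, silent = 0.20,
                                       nonsense = 0.05, splice_site = 0.04,
                                       nonstop = 0.01, indel = 0.08),
                       seed = 1) {
  assert_count(n_patients, "n_patients")
  assert_count(n_genes, "n_genes")
  if (!is.numeric(mutation_rate) || mutation_rate <= 0)
    stop("mutation_rate must be positive", call. = FALSE)
  if (driver_multiplier < 1)
    stop("driver_multiplier must be >= 1", call. = FALSE)
  assert_fraction(carrier_rate, "carrier_rate")
  assert_fraction(decoy_rate, "decoy_rate")
  assert_fraction(ranking_concordance, "ranking_concordance")
  if (!is.null(signature_mixture) &&
      (any(signature_mixture < 0) || sum(signature_mixture) <= 0))
    stop("Dirichlet concentrations must be non-negative with positive sum",
         call. = FALSE)
  if (!is.null(gene_lengths)) {
    if (length(gene_lengths) != n_genes || is.null(names(gene_lengths)) ||
        any(gene_lengths <= 0))
      stop("gene_lengths must be a named positive vector of length n_genes",
           call. = FALSE)
  }
  stopifnot(abs(sum(class_probs) - 1) < 1e-8, abs(sum(smoking_probs) - 1) < 1e-8)
  structure(list(
    n_patients = n_patients, n_genes = n_genes, gene_lengths = gene_lengths,
    mutation_rate = mutation_rate, driver_genes = driver_genes,
    driver_multiplier = driver_multiplier,
    signature_mixture = signature_mixture, carrier_rate = carrier_rate,
    decoy_rate = decoy_rate, susceptibility_genes = susceptibility_genes,
    ranking_concordance = ranking_concordance,
    driver_rank_boost = driver_rank_boost, smoking_probs = smoking_probs,
    class_probs = class_probs, seed = as.integer(seed)),
    class = "sim_config")
}

resolve_genes <- function(spec, gene_names, from_tail = FALSE) {
  if (is.null(spec)) return(character(0))
  if (is.numeric(spec)) {
    k <- min(as.integer(spec), length(gene_names))
    if (from_tail) return(rev(gene_names)[seq_len(k)])
    return(gene_names[seq_len(k)])
  }
  spec <- as.character(spec)
  if (!all(spec %in% gene_names))
    stop("gene subset names not found among simulated genes", call. = FALSE)
  spec
}

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

channel_to_record <- function(channel) {
  ## "A[C>A]G" -> ref "C", alt "A", context3 "ACG"
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  f <- substr(channel, 1, 1)
  t <- substr(channel, 7, 7)
  list(ref = ref, alt = alt, context3 = paste0(f, ref, t))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Per patient: a Poisson mutation count with the configured mean; genes
#' drawn with probability proportional to coding length, multiplied by the
#' planted-driver factor; SBS channels drawn from the patient's own
#' Dirichlet mixture of the catalog signature profiles; about half of all
#' SNV records are emitted on the purine strand so downstream catalog
#' building must canonicalize. Genomic coordinates are synthetic
#' (sequential within per-gene footprints on round-robin chromosomes); the
#' 3-mer context travels with each record so no reference genome is needed.
#' Carriers receive exactly one qualifying germline variant in a
#' susceptibility gene; a configurable fraction of non-carriers receives a
#' decoy variant failing exactly one filter criterion, so every branch of
#' the germline cascade is exercised.
#'
#' The `truth` block records planted exposures (rows sum to 1), the driver
#' set, the carrier set, and all derived stage seeds. The same config
#' (including seed) always reproduces the identical cohort.
#'
#' @param config a [sim_config()].
#' @param catalog 96 x K signature catalog; default
#'   [synthetic_signature_catalog()] with 5 signatures.
#' @return object of class `synthetic_cohort`: list with `patients`,
#'   `somatic`, `germline`, `truth`, `config`.
#' @export
generate_cohort <- function(config, catalog = synthetic_signature_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  catalog <- validate_signature_catalog(catalog)
  K <- ncol(catalog)
  alpha <- config$signature_mixture %||% rep(1, K)
  if (length(alpha) != K)
    stop("signature_mixture length (", length(alpha),
         ") does not match catalog signatures (", K, ")", call. = FALSE)
  if (config$n_genes < 1) stop("empty gene set", call. = FALSE)

  gene_names <- sprintf("G%04d", seq_len(config$n_genes))
  seeds <- c(lengths = derive_seed(config$seed, "gene_lengths"),
             patients = derive_seed(config$seed, "patients"),
             exposures = derive_seed(config$seed, "exposures"),
             somatic = derive_seed(config$seed, "somatic"),
             germline = derive_seed(config$seed, "germline"))

  gene_lengths <- config$gene_lengths
  if (is.null(gene_lengths)) {
    set.seed(seeds[["lengths"]])
    gene_lengths <- setNames(
      200 + round(rgamma(config$n_genes, shape = 3, scale = 500)), gene_names)
  } else gene_names <- names(gene_lengths)

  drivers <- resolve_genes(config$driver_genes, gene_names)
  susceptibility <- resolve_genes(
    config$susceptibility_genes %||% min(152, config$n_genes),
    gene_names, from_tail = TRUE)

  ## -- patient metadata -------------------------------------------------
  set.seed(seeds[["patients"]])
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  patients <- data.frame(
    patient_id = ids,
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.56, 0.44)),
    age = pmin(90, pmax(30, round(rnorm(n, 58.8, 14.5)))),
    smoking = sample(names(config$smoking_probs), n, TRUE,
                     prob = config$smoking_probs),
    stage = sample(c("I", "II", "III", "IV"), n, TRUE,
                   prob = c(0.08, 0.08, 0.20, 0.64)),
    stringsAsFactors = FALSE)

  ## -- planted exposures ------------------------------------------------
  set.seed(seeds[["exposures"]])
  exposures <- rdirichlet(n, alpha)
  dimnames(exposures) <- list(ids, colnames(catalog))

  ## -- somatic mutations ------------------------------------------------
  set.seed(seeds[["somatic"]])
  gene_weight <- gene_lengths
  gene_weight[drivers] <- gene_weight[drivers] * config$driver_multiplier
  gene_prob <- gene_weight / sum(gene_weight)
  counts <- rpois(n, config$mutation_rate)
  total <- sum(counts)
  pat_idx <- rep(seq_len(n), counts)
  gene_idx <- sample.int(length(gene_names), total, TRUE, prob = gene_prob)
  vclass <- sample(names(config$class_probs), total, TRUE,
                   prob = config$class_probs)
  channels <- sbs96_channels()
  channel_idx <- integer(total)
  for (i in seq_len(n)) {
    sel <- which(pat_idx == i)
    if (!length(sel)) next
    mix <- as.numeric(catalog %*% exposures[i, ])
    channel_idx[sel] <- sample.int(96, length(sel), TRUE, prob = mix)
  }
  rec <- channel_to_record(channels[channel_idx])
  ref <- rec$ref; alt <- rec$alt; context3 <- rec$context3
  ## emit roughly half the SNVs on the purine strand
  flip <- runif(total) < 0.5
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  context3[flip] <- revcomp(context3[flip])
  is_indel <- vclass == "indel"
  ref[is_indel] <- "A"
  alt[is_indel] <- "AT"
  context3[is_indel] <- NA_character_
  gene_start <- setNames(cumsum(c(0, utils::head(gene_lengths, -1))) + 1,
                         gene_names)
  offset <- stats::ave(seq_len(total), gene_idx, FUN = seq_along)
  somatic <- data.frame(
    patient_id = ids[pat_idx],
    gene = gene_names[gene_idx],
    chrom = as.character((gene_idx - 1L) %% 22L + 1L),
    pos = unname(gene_start[gene_idx] + offset - 1L),
    ref = ref, alt = alt, variant_class = vclass, context3 = context3,
    stringsAsFactors = FALSE)

  ## -- germline variants ------------------------------------------------
  set.seed(seeds[["germline"]])
  carrier <- rbinom(n, 1, config$carrier_rate) == 1
  carriers <- ids[carrier]
  qualifying <- function(pid) data.frame(
    patient_id = pid, gene = sample(susceptibility, 1),
    clinical_significance = sample(c("Pathogenic", "Likely pathogenic"), 1),
    af_gnomad = runif(1, 0, 1e-3), af_1000g = runif(1, 0, 1e-3),
    cadd_phred = runif(1, 25, 40), polyphen = "Probably damaging",
    sift = "Deleterious", review_pass = TRUE, stringsAsFactors = FALSE)
  ## decoys each fail exactly one criterion of the cascade
  decoy_kinds <- c("significance", "af", "gene_list", "review",
                   "insufficient_predictors")
  decoy <- function(pid, kind) {
    v <- qualifying(pid)
    switch(kind,
      significance = { v$clinical_significance <- "other" },
      af = { v$af_gnomad <- 0.05 },                       # boundary: excluded
      gene_list = { v$gene <- "NOTONLIST" },
      review = { v$review_pass <- FALSE },
      insufficient_predictors = {
        v$clinical_significance <- "Uncertain significance"
        v$polyphen <- "Benign"; v$sift <- "Tolerated"     # CADD alone met
      })
    v
  }
  rows <- lapply(carriers, qualifying)
  noncarriers <- ids[!carrier]
  if (length(noncarriers)) {
    gets_decoy <- runif(length(noncarriers)) < config$decoy_rate
    kinds <- decoy_kinds[(seq_along(noncarriers) - 1L) %% 5L + 1L]
    rows <- c(rows, Map(decoy, noncarriers[gets_decoy],
                        kinds[gets_decoy]))
  }
  germline <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), gene = character(0),
               clinical_significance = character(0), af_gnomad = numeric(0),
               af_1000g = numeric(0), cadd_phred = numeric(0),
               polyphen = character(0), sift = character(0),
               review_pass = logical(0), stringsAsFactors = FALSE)
  rownames(germline) <- NULL

  structure(list(
    patients = patients, somatic = somatic, germline = germline,
    truth = list(exposures = exposures, drivers = drivers,
                 carriers = carriers, susceptibility = susceptibility,
                 gene_lengths = gene_lengths, seeds = seeds),
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$patients), "patients,",
      nrow(x$somatic), "somatic records,", nrow(x$germline),
      "germline records,", length(x$truth$drivers), "planted drivers,",
      length(x$truth$carriers), "planted carriers\n")
  invisible(x)
}

#' Generate three tool ranking tables with tunable concordance
#'
#' Emulates the per-gene orderings of three external positive-selection
#' tools. Each tool's score mixes a shared latent driver score with
#' tool-specific noise: `score_t = sqrt(c) * latent + sqrt(1-c) * noise_t`
#' with `c = ranking_concordance`, so c = 1 yields identical orders and
#' c = 0 independent random orders. Planted drivers receive
#' `driver_rank_boost` added to the shared latent score, so with a large
#' boost they dominate every tool's top decile.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config the same [sim_config()] (for concordance, boost, seed).
#' @param tools three tool labels.
#' @return list of three ranking tables.
#' @export
generate_rankings <- function(cohort, config = cohort$config,
                              tools = c("toolA", "toolB", "toolC")) {
  stopifnot(inherits(cohort, "synthetic_cohort"), length(tools) == 3L)
  genes <- names(cohort$truth$gene_lengths)
  cc <- config$ranking_concordance
  set.seed(derive_seed(config$seed, "rankings"))
  latent <- rnorm(length(genes)) +
    config$driver_rank_boost * (genes %in% cohort$truth$drivers)
  lapply(tools, function(tl) {
    noise <- rnorm(length(genes))
    ranking_table(tl, genes, sqrt(cc) * latent + sqrt(1 - cc) * noise)
  })
}
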
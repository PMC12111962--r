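## Configuration-driven orchestration of the full comparative analysis:
## synthesize -> germline -> signatures -> drivers -> compare, with seed
## management and a machine-readable JSON run report.

PIPELINE_STAGES <- c("simulate", "germline", "signatures", "drivers",
                     "compare")

default_params <- function() {
  list(af_threshold = 0.05, fraction = 0.10, min_tools = 2L, B = 2000L,
       capture_mb = 37.5, presence_epsilon = 0, correction = "bonferroni")
}

#' Load a pipeline configuration from YAML or a list
#'
#' Top-level keys: `seed` (master seed), `stages` (subset of
#' simulate/germline/signatures/drivers/compare; defaults to every stage
#' whose inputs are available), `simulate` (a [sim_config()] argument list
#' for the query cohort), `reference` (ditto for a reference cohort),
#' `inputs` (paths: `somatic`, `germline`, `metadata`, `gene_list`,
#' `rankings`, `catalog`) for running on real tables instead of simulating,
#' `params` (thresholds: `af_threshold`, `fraction`, `min_tools`, `B`,
#' `capture_mb`, `presence_epsilon`, `correction`), and `outdir`.
#'
#' @param config list or path to a YAML file.
#' @return normalized config list of class `run_config`.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config$params <- utils::modifyList(default_params(),
                                     config$params %||% list())
  if (!is.null(config$stages)) {
    bad <- setdiff(config$stages, PIPELINE_STAGES)
    if (length(bad))
      stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(config, class = "run_config")
}

build_sim <- function(block, seed) {
  block <- block %||% list()
  if (is.null(block$seed)) block$seed <- seed
  do.call(sim_config, block)
}

#' Run the full comparative pipeline
#'
#' Executes the enabled stages in dependency order on either synthetic
#' cohorts (a `simulate` block, optionally a `reference` block) or tables
#' read from `inputs` paths. Identical config and master seed reproduce an
#' identical report; every derived stage seed is recorded in it. A stage
#' explicitly listed in `stages` whose inputs are missing raises an error
#' naming the stage; stages not enabled are recorded as skipped. Output
#' files (cohort TSVs and the JSON report) are written to `outdir` only
#' after every enabled stage has completed.
#'
#' @param config list or YAML path (see [load_run_config()]).
#' @return run report (list of class `run_report`), invisibly written to
#'   `outdir/report.json` when `outdir` is set.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  p <- cfg$params
  explicit <- !is.null(cfg$stages)
  enabled <- cfg$stages %||% PIPELINE_STAGES
  simulated <- !is.null(cfg$simulate) || is.null(cfg$inputs)
  report <- list(
    tool = "oncocohort",
    version = as.character(utils::packageVersion("oncocohort")),
    seed = cfg$seed, params = p, stages = list(), warnings = character(0))
  stages <- list()
  skip <- function(name, reason) list(status = "skipped", reason = reason)

  need <- function(stage, ok, what) {
    if (ok) return(TRUE)
    if (explicit && stage %in% enabled)
      stop("stage '", stage, "': missing required input (", what, ")",
           call. = FALSE)
    FALSE
  }

  catalog <- if (!is.null(cfg$inputs$catalog))
    read_signature_catalog(cfg$inputs$catalog) else
    synthetic_signature_catalog()

  ## -- simulate ---------------------------------------------------------
  query <- NULL; reference <- NULL
  if ("simulate" %in% enabled && simulated) {
    qcfg <- build_sim(cfg$simulate, derive_seed(cfg$seed, "query"))
    query <- generate_cohort(qcfg, catalog)
    stages$simulate <- list(
      status = "completed",
      query = list(n_patients = nrow(query$patients),
                   n_somatic = nrow(query$somatic),
                   n_germline = nrow(query$germline),
                   seeds = as.list(query$truth$seeds)))
    if (!is.null(cfg$reference)) {
      rcfg <- build_sim(cfg$reference, derive_seed(cfg$seed, "reference"))
      reference <- generate_cohort(rcfg, catalog)
      stages$simulate$reference <- list(
        n_patients = nrow(reference$patients),
        n_somatic = nrow(reference$somatic),
        n_germline = nrow(reference$germline),
        seeds = as.list(reference$truth$seeds))
    }
  } else stages$simulate <- skip("simulate",
    if (simulated) "disabled" else "running on file inputs")

  ## assemble the query tables from files when not simulating
  somatic <- query$somatic
  germline <- query$germline
  patient_ids <- query$patients$patient_id
  gene_list <- query$truth$susceptibility
  gene_lengths <- query$truth$gene_lengths
  if (!simulated) {
    if (!is.null(cfg$inputs$somatic)) {
      somatic <- read_maf_tsv(cfg$inputs$somatic)
      patient_ids <- sort(unique(somatic$patient_id))
    }
    if (!is.null(cfg$inputs$germline))
      germline <- read_germline_tsv(cfg$inputs$germline)
    if (!is.null(cfg$inputs$metadata))
      patient_ids <- read_metadata_tsv(cfg$inputs$metadata)$patient_id
    if (!is.null(cfg$inputs$gene_list))
      gene_list <- read_gene_list(cfg$inputs$gene_list)
  }

  ## -- germline ---------------------------------------------------------
  if ("germline" %in% enabled &&
      need("germline", !is.null(germline) && !is.null(gene_list),
           "germline variants and a gene list")) {
    cls <- classify_variants(germline, gene_list, p$af_threshold)
    carr <- carrier_table(cls, patient_ids)
    out <- list(status = "completed",
                n_variants = nrow(cls),
                n_retained = sum(startsWith(cls$decision, "retained")),
                carriers = sum(carr$carrier),
                n_patients = length(patient_ids),
                carrier_rate = carrier_proportion(carr, length(patient_ids)))
    if (!is.null(reference)) {
      rcls <- classify_variants(reference$germline,
                                reference$truth$susceptibility,
                                p$af_threshold)
      rcarr <- carrier_table(rcls, reference$patients$patient_id)
      out$reference_carrier_rate <-
        carrier_proportion(rcarr, nrow(reference$patients))
      out$carrier_rate_p <- compare_carrier_rates(
        sum(carr$carrier), length(patient_ids),
        sum(rcarr$carrier), nrow(reference$patients))
    }
    stages$germline <- out
  } else stages$germline <- skip("germline", "disabled or no germline input")

  ## -- signatures -------------------------------------------------------
  exposures <- NULL; ref_exposures <- NULL
  if ("signatures" %in% enabled &&
      need("signatures", !is.null(somatic), "a somatic mutation table")) {
    cat96 <- build_catalog(somatic, patient_ids)
    exposures <- refit_exposures(cat96, catalog)
    out <- list(status = "completed",
                n_snv = sum(cat96),
                summary = as.list(cohort_signature_summary(exposures)))
    if (!is.null(reference)) {
      rcat <- build_catalog(reference$somatic,
                            reference$patients$patient_id)
      ref_exposures <- refit_exposures(rcat, catalog)
      out$reference_summary <-
        as.list(cohort_signature_summary(ref_exposures))
      sigs <- colnames(exposures$proportions)
      m_tests <- length(sigs)
      contrasts <- lapply(sigs, function(s) {
        cmp <- compare_signature_between_cohorts(
          exposures$proportions[exposures$defined, s],
          ref_exposures$proportions[ref_exposures$defined, s], m_tests)
        c(list(signature = s), cmp)
      })
      out$contrasts <- contrasts
      presA <- signature_presence(exposures, p$presence_epsilon)
      presB <- signature_presence(ref_exposures, p$presence_epsilon)
      out$presence <- lapply(sigs, function(s) list(
        signature = s,
        present_query = unname(presA$present[s]), n_query = presA$n,
        present_reference = unname(presB$present[s]), n_reference = presB$n,
        p = signature_presence_test(presA$present[s], presA$n,
                                    presB$present[s], presB$n)))
    }
    stages$signatures <- out
  } else stages$signatures <- skip("signatures",
                                   "disabled or no somatic input")

  ## -- drivers ----------------------------------------------------------
  if ("drivers" %in% enabled &&
      need("drivers", simulated || !is.null(cfg$inputs$rankings),
           "ranking tables")) {
    rankings <- if (!simulated && !is.null(cfg$inputs$rankings))
      read_rankings_tsv(cfg$inputs$rankings) else
      generate_rankings(query)
    cons <- multi_tool_coincidence_test(
      rankings, p$fraction, p$min_tools, p$B,
      seed = derive_seed(cfg$seed, "coincidence"))
    out <- list(status = "completed",
                joint_set = cons$joint_set,
                observed_stat = cons$observed_stat,
                p_empirical = cons$p_empirical,
                B = cons$B, seed = cons$seed,
                null_summary = null_summary(cons$null_stats))
    if (!is.null(reference)) {
      ref_rankings <- generate_rankings(reference)
      ref_cons <- multi_tool_coincidence_test(
        ref_rankings, p$fraction, p$min_tools, p$B,
        seed = derive_seed(cfg$seed, "coincidence_ref"))
      universe <- intersect(cons$universe, ref_cons$universe)
      ov <- cross_cohort_overlap_test(
        intersect(cons$joint_set, universe),
        intersect(ref_cons$joint_set, universe), universe, p$B,
        seed = derive_seed(cfg$seed, "overlap"))
      out$overlap <- list(
        observed_overlap = ov$observed_overlap,
        expected_null = ov$expected_null,
        p_empirical = ov$p_empirical,
        size_a = ov$size_a, size_b = ov$size_b,
        size_universe = ov$size_universe, B = ov$B, seed = ov$seed,
        null_summary = null_summary(ov$null_stats))
    }
    stages$drivers <- out
  } else stages$drivers <- skip("drivers", "disabled or no rankings")

  ## -- compare ----------------------------------------------------------
  if ("compare" %in% enabled &&
      need("compare", !is.null(somatic), "a somatic mutation table")) {
    freq <- gene_frequency_table(somatic, length(patient_ids))
    tmb <- compute_tmb(somatic, p$capture_mb, patient_ids)
    out <- list(status = "completed",
                median_tmb = tmb$median_tmb,
                top_frequencies = utils::head(freq, 10))
    if (!is.null(reference)) {
      rfreq <- gene_frequency_table(reference$somatic,
                                    nrow(reference$patients))
      cmp <- suppressWarnings(compare_gene_frequencies(
        freq, rfreq, correction = p$correction))
      rtmb <- compute_tmb(reference$somatic, p$capture_mb,
                          reference$patients$patient_id)
      out$reference_median_tmb <- rtmb$median_tmb
      out$n_genes_compared <- nrow(cmp)
      sig <- cmp[cmp$p_adjusted < 0.05, , drop = FALSE]
      out$significant_genes <- sig[order(sig$p_adjusted, sig$gene), ]
    }
    stages$compare <- out
  } else stages$compare <- skip("compare", "disabled or no somatic input")

  report$stages <- stages
  report <- structure(report, class = c("run_report", "list"))
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(query)) write_cohort_tsv(query, cfg$outdir, "query")
    if (!is.null(reference))
      write_cohort_tsv(reference, cfg$outdir, "reference")
    write_run_report(report, file.path(cfg$outdir, "report.json"))
  }
  report
}

null_summary <- function(x) {
  q <- quantile(x, c(0.5, 0.95, 0.99), names = FALSE)
  list(count = length(x), mean = mean(x), median = q[1], q95 = q[2],
       q99 = q[3], max = max(x))
}

#' Serialize / read back a run report as JSON
#'
#' Serialization is deterministic (fixed 15 significant digits), so two runs
#' with the same config and master seed produce byte-identical files.
#'
#' @param report a `run_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_run_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = I(15),
                           pretty = TRUE, dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_run_report
#' @export
read_run_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("oncocohort run report (seed", x$seed, ")\n")
  for (s in names(x$stages))
    cat(sprintf("  %-10s %s\n", s, x$stages[[s]]$status))
  invisible(x)
}
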
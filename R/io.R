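## Plain-text table dialects: MAF-like somatic TSV, germline TSV, patient
## metadata TSV, ranking TSV, gene lists.

MAF_COLUMNS <- c("patient_id", "gene", "chrom", "pos", "ref", "alt",
                 "variant_class", "context3")

read_table_checked <- function(path, required, what) {
  if (!file.exists(path))
    stop(what, " file not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read / write the MAF-like somatic mutation TSV
#'
#' Tab-separated, one mutation per row, 1-based coordinates, columns
#' `patient_id, gene, chrom, pos, ref, alt, variant_class, context3`
#' (`context3` may be NA for indels).
#'
#' @param path file path.
#' @return data frame of mutations.
#' @export
read_maf_tsv <- function(path) {
  df <- read_table_checked(path, MAF_COLUMNS, "somatic MAF-like")
  if (any(!is.na(df$pos) & df$pos < 1))
    stop("somatic file '", path, "': positions must be 1-based (column pos)",
         call. = FALSE)
  df
}

#' @rdname read_maf_tsv
#' @param somatic mutation data frame.
#' @export
write_maf_tsv <- function(somatic, path) {
  write.table(somatic[MAF_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

GERMLINE_COLUMNS <- c("patient_id", "gene", "clinical_significance",
                      "cadd_phred", "polyphen", "sift", "review_pass")

#' Read / write the germline variant TSV
#'
#' One annotated variant per row; population allele-frequency columns are
#' prefixed `af_` (any number of populations).
#'
#' @param path file path.
#' @return data frame of germline variants.
#' @export
read_germline_tsv <- function(path) {
  df <- read_table_checked(path, GERMLINE_COLUMNS, "germline variant")
  if (!any(startsWith(names(df), "af_")))
    stop("germline file '", path, "' has no 'af_*' column", call. = FALSE)
  df$review_pass <- as.logical(df$review_pass)
  df
}

#' @rdname read_germline_tsv
#' @param variants germline variant data frame.
#' @export
write_germline_tsv <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a ranking TSV (`tool, gene, score, rank`)
#'
#' The reader validates that each tool's ranks are a permutation of 1..G.
#'
#' @param path file path.
#' @return list of ranking tables, one per tool.
#' @export
read_rankings_tsv <- function(path) {
  df <- read_table_checked(path, c("tool", "gene", "score", "rank"),
                           "ranking")
  out <- lapply(split(df, df$tool), function(r) {
    rownames(r) <- NULL
    validate_ranking(r)
    r
  })
  out[order(names(out))]
}

#' @rdname read_rankings_tsv
#' @param rankings list of ranking tables.
#' @export
write_rankings_tsv <- function(rankings, path) {
  df <- do.call(rbind, rankings)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the patient metadata TSV
#'
#' @param path file path.
#' @return data frame with at least `patient_id`.
#' @export
read_metadata_tsv <- function(path) {
  read_table_checked(path, "patient_id", "patient metadata")
}

#' @rdname read_metadata_tsv
#' @param patients metadata data frame.
#' @export
write_metadata_tsv <- function(patients, path) {
  write.table(patients, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line, `#` comments allowed)
#'
#' @param path file path.
#' @return character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path))
    stop("gene list file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("gene list '", path, "' is empty", call. = FALSE)
  unique(x)
}

#' Write a synthetic cohort's tables to a directory
#'
#' Emits the MAF-like somatic TSV, germline TSV and metadata TSV dialects.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisible vector of the paths written.
#' @export
write_cohort_tsv <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    somatic = file.path(dir, paste0(prefix, "_somatic.tsv")),
    germline = file.path(dir, paste0(prefix, "_germline.tsv")),
    metadata = file.path(dir, paste0(prefix, "_metadata.tsv")))
  write_maf_tsv(cohort$somatic, paths[["somatic"]])
  write_germline_tsv(cohort$germline, paths[["germline"]])
  write_metadata_tsv(cohort$patients, paths[["metadata"]])
  invisible(paths)
}
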
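## SBS-96 channel machinery: canonical labels, canonicalization of SNVs to
## the pyrimidine-referenced strand, and patient x channel catalog matrices.

DNA_BASES <- c("A", "C", "G", "T")
SBS_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 single-base-substitution channel labels in COSMIC order
#'
#' Six pyrimidine-referenced substitutions (C>A, C>G, C>T, T>A, T>C, T>G),
#' each expanded over the 16 combinations of 5' and 3' flanking bases in
#' alphabetical order, e.g. `"A[C>A]A"`, `"A[C>A]C"`, ..., `"T[T>G]T"`.
#'
#' @return character vector of length 96.
#' @export
sbs96_channels <- function() {
  unlist(lapply(SBS_SUBS, function(s)
    unlist(lapply(DNA_BASES, function(f)
      paste0(f, "[", s, "]", DNA_BASES)))))
}

revcomp <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

#' Canonicalize an SNV to its SBS-96 channel
#'
#' A substitution is classified not just by the mutated base but by its
#' immediate 5' and 3' flanking bases. Substitutions reported on the purine
#' strand (reference A or G) are reverse-complemented so that every channel
#' is referenced to a pyrimidine (C or T); the two strand representations of
#' one event therefore map to the same channel.
#'
#' Vectorized. Records with ambiguous bases (anything outside A/C/G/T),
#' `ref == alt`, or a context whose middle base disagrees with `ref` get
#' `NA` and are counted as skipped by [build_catalog()].
#'
#' @param ref,alt single reference and alternate bases.
#' @param context3 3-mer centered on the site, middle base equal to `ref`.
#' @return channel labels (character), `NA` where invalid.
#' @examples
#' canonicalize_snv("C", "A", "ACA")  # "A[C>A]A"
#' canonicalize_snv("G", "T", "TGT")  # "A[C>A]A" via reverse complement
#' @export
canonicalize_snv <- function(ref, alt, context3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context3) == n)
  ref <- toupper(ref); alt <- toupper(alt); context3 <- toupper(context3)
  ok <- !is.na(ref) & !is.na(alt) & !is.na(context3) &
    ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt &
    nchar(context3) == 3L & substr(context3, 2, 2) == ref &
    grepl("^[ACGT]{3}$", context3)
  out <- rep(NA_character_, n)
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; cx <- context3[ok]
  flip <- r %in% c("A", "G")
  if (any(flip)) {
    cx[flip] <- revcomp(cx[flip])
    r[flip] <- chartr("ACGT", "TGCA", r[flip])
    a[flip] <- chartr("ACGT", "TGCA", a[flip])
  }
  out[ok] <- paste0(substr(cx, 1, 1), "[", r, ">", a, "]", substr(cx, 3, 3))
  out
}

is_snv <- function(ref, alt) {
  !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    toupper(ref) %in% DNA_BASES & toupper(alt) %in% DNA_BASES &
    toupper(ref) != toupper(alt)
}

#' Build a patient x 96-channel substitution catalog
#'
#' Counts canonicalized SNVs per patient and channel. Indels and any record
#' that is not a clean single-base substitution are excluded, so each row sum
#' equals the number of valid SNVs for that patient. Records carrying N or an
#' inconsistent context are skipped with a message.
#'
#' @param mutations data frame with columns `patient_id`, `ref`, `alt`,
#'   `context3` (further columns ignored).
#' @param patients optional character vector fixing the row set and order;
#'   defaults to the patients present, sorted. Patients with no SNV get a
#'   zero row.
#' @return integer matrix, patients x 96, columns in [sbs96_channels()] order.
#' @export
build_catalog <- function(mutations, patients = NULL) {
  need <- c("patient_id", "ref", "alt", "context3")
  miss <- setdiff(need, names(mutations))
  if (length(miss))
    stop("mutations table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(patients)) patients <- sort(unique(as.character(mutations$patient_id)))
  channels <- sbs96_channels()
  snv <- is_snv(mutations$ref, mutations$alt)
  m <- mutations[snv, , drop = FALSE]
  lab <- canonicalize_snv(m$ref, m$alt, m$context3)
  n_bad <- sum(is.na(lab))
  if (n_bad > 0)
    message(n_bad, " SNV record(s) with invalid base/context skipped")
  keep <- !is.na(lab)
  tab <- table(factor(as.character(m$patient_id)[keep], levels = patients),
               factor(lab[keep], levels = channels))
  matrix(as.integer(tab), nrow = length(patients), ncol = 96L,
         dimnames = list(patients, channels))
}
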
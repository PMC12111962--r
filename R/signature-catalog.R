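## Signature catalogs: COSMIC-style SBS text format IO and a synthetic
## catalog for tests and simulations.

validate_signature_catalog <- function(sigs, tol = 1e-8) {
  if (!is.matrix(sigs) || nrow(sigs) != 96L)
    stop("a signature catalog must be a 96 x K matrix", call. = FALSE)
  if (is.null(rownames(sigs)) || !setequal(rownames(sigs), sbs96_channels()))
    stop("signature catalog rows must be the 96 SBS channel labels",
         call. = FALSE)
  if (any(sigs < 0))
    stop("signature profiles must be non-negative", call. = FALSE)
  cs <- colSums(sigs)
  if (any(abs(cs - 1) > tol))
    stop("each signature profile must sum to 1 (tolerance ", tol, ")",
         call. = FALSE)
  sigs[sbs96_channels(), , drop = FALSE]
}

#' Read a signature catalog in COSMIC SBS text format
#'
#' Tab-separated, a `Type` column holding the 96 channel labels (any order)
#' and one column per signature; profiles must be non-negative and sum to 1.
#' Rows are reordered to the canonical channel order.
#'
#' @param path file path.
#' @return numeric 96 x K matrix with channel rownames.
#' @export
read_signature_catalog <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"Type" %in% names(df))
    stop("signature catalog '", path, "' lacks a 'Type' column", call. = FALSE)
  m <- as.matrix(df[setdiff(names(df), "Type")])
  rownames(m) <- df$Type
  validate_signature_catalog(m)
}

#' Write a signature catalog in COSMIC SBS text format
#'
#' @param sigs 96 x K matrix with channel rownames.
#' @param path output path.
#' @export
write_signature_catalog <- function(sigs, path) {
  sigs <- validate_signature_catalog(sigs)
  df <- data.frame(Type = rownames(sigs), sigs, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' A synthetic, clearly non-COSMIC signature catalog
#'
#' Deterministically constructs K well-separated SBS-96 profiles: signature k
#' places a fraction `block_weight` of its mass uniformly on its own
#' contiguous block of channels and spreads the remainder uniformly over all
#' 96, so profiles overlap but remain identifiable. Intended for simulations
#' and tests; it does not reproduce any COSMIC signature and the names say so.
#'
#' @param K number of signatures (2..12).
#' @param block_weight fraction of mass on the signature's own block.
#' @return 96 x K matrix, columns named `SynSig1..SynSigK`.
#' @export
synthetic_signature_catalog <- function(K = 5, block_weight = 0.75) {
  assert_count(K, "K")
  if (K < 2 || K > 12) stop("K must be between 2 and 12", call. = FALSE)
  assert_fraction(block_weight, "block_weight")
  channels <- sbs96_channels()
  block <- cut(seq_len(96), breaks = K, labels = FALSE)
  sigs <- vapply(seq_len(K), function(k) {
    p <- rep((1 - block_weight) / 96, 96)
    idx <- which(block == k)
    p[idx] <- p[idx] + block_weight / length(idx)
    p
  }, numeric(96))
  dimnames(sigs) <- list(channels, paste0("SynSig", seq_len(K)))
  sigs
}
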
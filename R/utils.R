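#' Derive a stage-specific child seed from a master seed
#'
#' All randomness in the package flows from one master seed. Each stage
#' (patient metadata, somatic draw, germline draw, rankings, resampling
#' nulls) re-seeds from a child seed derived deterministically from the
#' master seed and a stage tag, so stages can be re-run in isolation and
#' adding records to one stage never perturbs another.
#'
#' @param master integer master seed.
#' @param tag character stage tag.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.character(tag), length(tag) == 1L, nzchar(tag))
  codes <- utf8ToInt(tag)
  h <- 0
  for (k in seq_along(codes)) h <- (h * 131 + codes[k]) %% 2147483629
  as.integer((abs(as.double(master)) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## single source for the variant classes counted as non-synonymous
## (splice site, missense, nonsense, nonstop)
nonsyn_classes <- function() c("missense", "nonsense", "nonstop", "splice_site")

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      (positive && x <= 0) || (!positive && x < 0))
    stop(sprintf("'%s' must be a %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  invisible(as.integer(x))
}
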
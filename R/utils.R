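# Small shared helpers.

# Round-half-up (base round() is round-half-even); group sizes and mask
# budgets use this convention so 0.5 cases are deterministic and match the
# printed endpoint arithmetic (e.g. round(0.05 * 20) = 1).
round_half_up <- function(x) floor(x + 0.5)

# Truncated-normal initialiser (sd 0.02, truncated at +/- 2 sd), via inverse
# CDF so draws consume exactly `n` uniforms from the global RNG stream.
trunc_normal <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

# MD5 digest of a serialized R object (via tools::md5sum on a temp file;
# version-2 serialization keeps the byte stream stable across sessions).
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' Fingerprint a list of numeric arrays
#'
#' Deterministic hex digest of parameter values; identical weights give
#' identical digests. Used to verify teacher immutability and checkpoint
#' round-trips.
#'
#' @param params Named list of numeric arrays.
#' @return A character scalar.
#' @export
params_digest <- function(params) {
  params <- params[order(names(params))]
  object_digest(lapply(params, function(p) as.numeric(p)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
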
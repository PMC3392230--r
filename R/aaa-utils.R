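## Small shared numerics and bookkeeping helpers.

NUCS <- c("A", "C", "G", "T")

#' x * log(x) with the 0 * log(0) = 0 convention
#'
#' Workhorse for entropy-style likelihood sums (G statistic, binomial LOD).
#' Vectorised; preserves matrix shape.
#'
#' @param x non-negative numeric vector or matrix.
#' @return numeric of the same shape as `x`.
#' @keywords internal
xlogx <- function(x) {
  out <- x
  pos <- !is.na(x) & x > 0
  out[pos] <- x[pos] * log(x[pos])
  out[!is.na(x) & x == 0] <- 0
  out
}

#' Round half away from zero
#'
#' Display rounding used for report tables (base `round()` rounds half to
#' even, which does not match how published tables are typically rounded).
#'
#' @param x numeric.
#' @param digits integer number of decimal places.
#' @return numeric rounded half away from zero.
#' @export
#' @examples
#' round_half_away(9.8536, 1)  # 9.9
#' round_half_away(0.5, 0)     # 1
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Per-stage RNG streams: each pipeline stage draws from a seed derived from
## the master seed by a fixed offset, so e.g. changing the permutation count
## never perturbs the simulation draws. Offsets are fixed for the life of
## the package; results stay < 2^31 - 1.
STAGE_OFFSETS <- c(
  simulate = 1L, sex = 2L, reads = 3L, genotyper = 4L,
  sexscan = 5L, qtl = 6L, recomb = 7L, enrich = 8L, elements = 9L
)

#' Derive a stage-specific seed from a master seed
#'
#' @param seed master integer seed.
#' @param stage one of `names(radsexscan:::STAGE_OFFSETS)`.
#' @return an integer seed, distinct per stage, reproducible.
#' @export
stage_seed <- function(seed, stage) {
  stage <- match.arg(stage, names(STAGE_OFFSETS))
  as.integer((as.numeric(seed) + STAGE_OFFSETS[[stage]] * 100003) %%
               2147483647)
}

## stopifnot-with-message helper
check_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}

## Format a numeric column with 6 significant digits for TSV output.
fmt_sig6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}
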
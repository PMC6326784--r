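#' @import data.table
#' @importFrom stats dhyper p.adjust pchisq rbinom rexp rnbinom runif rbeta
#'   rgamma coef lm setNames
#' @importFrom utils packageVersion
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", ".I", "chrom", "pos", "n_meth", "n_unmeth", "coverage",
  "sample_id", "n_ok", "unit", "start", "end", "tile_id", "status", "q",
  "level", "class_", "icr", "icr_name", "genotype", "n_total",
  "meth_test", "meth_ctrl", "location", "n_member_cpgs", "percent",
  "allele1", "allele2", "pos0", "qual", "n_sites", "name", "tx_start",
  "tx_end", "strand", "prefix", "p", "anchor", "stated_pct", "group",
  "category", "n", "any_icr", "qualified", "Mt", "Ut", "Mc", "Uc", "pct",
  "pos2", "cov_factor"
))

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going up (so 0.5 -> 1), matching
#' the integer-percent reporting convention used for concordance fractions.
#' Base `round()` rounds half to even, which would report 82.5% as 82%.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count out of a total
#'
#' The single percent/rounding path used everywhere a fraction of counts is
#' reported: methylation percentages, state-class fractions, concordance
#' fractions.
#'
#' @param n numerator count.
#' @param total denominator count (> 0).
#' @param digits if non-`NULL`, round half-up to this many decimals.
#' @return percentage in `[0, 100]`.
#' @export
count_percent <- function(n, total, digits = NULL) {
  if (any(total <= 0)) stop("count_percent: total must be positive")
  out <- 100 * n / total
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
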
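#' Read a clone-by-CpG bisulfite matrix
#'
#' Tiny TSV format for clone-based bisulfite sequencing of one amplified
#' region: rows are sequenced clones, columns CpG positions, cells `1`
#' (methylated), `0` (unmethylated) or `.` (missing).
#'
#' @param path file path.
#' @return integer matrix with `NA` for missing calls.
#' @export
read_clone_matrix <- function(path) {
  raw <- fread(path, header = FALSE, sep = "\t", colClasses = "character")
  if (!nrow(raw)) stopf("%s: empty clone matrix", path)
  m <- as.matrix(raw)
  ok <- m %in% c("0", "1", ".")
  if (!all(ok)) stopf("%s: cells must be 0, 1 or .", path)
  out <- suppressWarnings(matrix(as.integer(m), nrow = nrow(m)))
  dimnames(out) <- NULL
  out
}

#' Region methylation percentage from sequenced clones
#'
#' Pools all clones and CpG positions of the matrix: 100 times the number of
#' methylated calls over the number of non-missing calls. Missing calls are
#' excluded from the denominator.
#'
#' @param mat clone-by-CpG matrix of 0/1 calls with `NA` for missing (see
#'   [read_clone_matrix]).
#' @return percentage in `[0, 100]`.
#' @export
clone_region_percent <- function(mat) {
  calls <- mat[!is.na(mat)]
  if (!length(calls)) stopf("clone_region_percent: all calls missing")
  if (!all(calls %in% c(0L, 1L)))
    stopf("clone_region_percent: calls must be 0/1/NA")
  100 * sum(calls == 1L) / length(calls)
}

#' Bisulfite conversion rate from non-CpG cytosines
#'
#' Unmethylated cytosines outside CpG context should read as T after
#' conversion; residual C reads measure conversion failure. The QC bound is
#' a conversion rate above 99%.
#'
#' @param n_converted non-CpG cytosines read as T.
#' @param n_unconverted non-CpG cytosines read as C.
#' @param qc_min QC threshold in percent (strict bound).
#' @return list with `rate` (percent) and logical `pass`.
#' @export
conversion_rate <- function(n_converted, n_unconverted, qc_min = 99) {
  total <- n_converted + n_unconverted
  if (total <= 0) stopf("conversion_rate: zero total cytosines")
  rate <- 100 * n_converted / total
  list(rate = rate, pass = rate > qc_min)
}

#' Protein half-life from a cycloheximide-chase decay curve
#'
#' Ordinary least squares of log intensity on time; under first-order decay
#' the slope is -ln(2) / t_half, so the half-life is ln(2) divided by the
#' negated slope. Densitometry noise is multiplicative, which makes the
#' log-linear fit the natural estimator with few time points; it is also
#' invariant to rescaling the loading-control normalisation. A
#' non-negative slope yields the sentinel `"no decay"` (`NA` half-life).
#'
#' @param times hours, strictly increasing, starting at 0; at least 3 points.
#' @param intensities normalized band intensities, all positive.
#' @return list with `half_life` (hours, `NA` if no decay), `slope`,
#'   `r_squared` and `decay` (logical).
#' @export
half_life <- function(times, intensities) {
  if (length(times) < 3L || length(times) != length(intensities))
    stopf("half_life: need >= 3 matched time points")
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0)
    stopf("half_life: times must be strictly increasing from 0")
  if (any(intensities <= 0))
    stopf("half_life: intensities must be positive")
  fit <- lm(log(intensities) ~ times)
  slope <- unname(coef(fit)[2])
  r2 <- suppressWarnings(summary(fit))$r.squared  # exact fits warn
  if (slope >= -1e-12)  # flat curves carry float-noise slopes near 0
    return(list(half_life = NA_real_, slope = slope, r_squared = r2,
                decay = FALSE))
  list(half_life = log(2) / (-slope), slope = slope, r_squared = r2,
       decay = TRUE)
}

#' Read a two-column decay curve TSV
#'
#' @param path TSV with header columns `time_h` and `intensity`.
#' @return list with `times` and `intensities`.
#' @export
read_decay_curve <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  if (!all(c("time_h", "intensity") %in% names(dt)))
    stopf("%s: need columns time_h, intensity", path)
  list(times = dt$time_h, intensities = dt$intensity)
}
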
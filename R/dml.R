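#' Two-group comparison of methylation call sets
#'
#' @param test list of [meth_call_set] for the test genotype.
#' @param control list of [meth_call_set] for the control genotype.
#' @param label comparison label, conventionally "test_vs_control"; the
#'   methylation difference is always test minus control, so "hypo" means
#'   loss in the test group.
#' @return object of class `comparison`.
#' @export
comparison <- function(test, control, label = "test_vs_control") {
  if (inherits(test, "meth_call_set")) test <- list(test)
  if (inherits(control, "meth_call_set")) control <- list(control)
  if (!length(test) || !length(control))
    stopf("comparison '%s': both groups must be non-empty", label)
  all_sets <- c(test, control)
  ok <- vapply(all_sets, inherits, logical(1), "meth_call_set")
  if (!all(ok)) stopf("groups must contain meth_call_set objects")
  ids <- vapply(all_sets, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stopf("comparison '%s': duplicate sample ids across groups", label)
  structure(list(test = test, control = control, label = label),
            class = "comparison")
}

#' @export
print.comparison <- function(x, ...) {
  cat(sprintf("<comparison> %s: %d test vs %d control samples\n",
              x$label, length(x$test), length(x$control)))
  invisible(x)
}

# long table of all calls in a comparison with group and sample columns
comparison_calls <- function(cmp) {
  grab <- function(sets, grp) rbindlist(lapply(sets, function(s)
    cbind(s$calls, sample_id = s$sample_id, group = grp)))
  rbindlist(list(grab(cmp$test, "test"), grab(cmp$control, "control")))
}

#' Qualify CpG sites for testing
#'
#' A site qualifies when it is observed with read coverage at least
#' `min_site_cov` in every sample of both groups.
#'
#' @param cmp a [comparison].
#' @param min_site_cov coverage threshold (default 20; inclusive).
#' @return `data.table` of qualified sites (`chrom`, `pos`), keyed.
#' @export
qualify_sites <- function(cmp, min_site_cov = 20L) {
  long <- comparison_calls(cmp)
  n_samples <- length(cmp$test) + length(cmp$control)
  qual <- long[n_meth + n_unmeth >= min_site_cov,
               .(n_ok = .N), by = .(chrom, pos)][n_ok == n_samples,
                                                 .(chrom, pos)]
  setkey(qual, chrom, pos)
  qual[]
}

#' Pooled group methylation percentage
#'
#' Coverage-weighted pooling: `100 * sum(n_meth) / sum(n_meth + n_unmeth)`
#' over all calls supplied (not the mean of per-sample percentages), matching
#' the count-based tests.
#'
#' @param n_meth,n_unmeth methylated/unmethylated read counts across a group.
#' @return pooled percentage.
#' @export
group_percent <- function(n_meth, n_unmeth) {
  total <- sum(n_meth) + sum(n_unmeth)
  if (total <= 0) stopf("group_percent: zero total coverage")
  100 * sum(n_meth) / total
}

#' Two-sided Fisher exact test on pooled counts
#'
#' Exact two-sided p-value for a 2x2 table of (methylated, unmethylated)
#' reads in (test, control): the hypergeometric probabilities of all tables
#' with the observed margins that are no more probable than the observed one
#' are summed. Used for 1-vs-1 comparisons without replicates.
#'
#' @param meth_test,unmeth_test pooled test-group read counts.
#' @param meth_ctrl,unmeth_ctrl pooled control-group read counts.
#' @return two-sided p-value; degenerate tables (a zero margin) return 1 with
#'   a warning.
#' @export
test_unit_fisher <- function(meth_test, unmeth_test, meth_ctrl, unmeth_ctrl) {
  m <- meth_test + unmeth_test     # test-row margin
  n <- meth_ctrl + unmeth_ctrl     # control-row margin
  k <- meth_test + meth_ctrl       # methylated-column margin
  u <- unmeth_test + unmeth_ctrl
  if (m == 0 || n == 0 || k == 0 || u == 0) {
    warnf("test_unit_fisher: degenerate margin, p = 1")
    return(1)
  }
  x <- max(0L, k - n):min(k, m)    # all feasible methylated-in-test counts
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(meth_test, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# closed-form binomial log-likelihood at pooled proportion
binom_ll <- function(M, U, p) {
  lm_ <- ifelse(M > 0, M * log(p), 0)
  lu_ <- ifelse(U > 0, U * log1p(-p), 0)
  lm_ + lu_
}

#' Binomial logistic likelihood-ratio test (replicate-aware)
#'
#' Logistic regression of the methylated proportion on a group indicator
#' with grouped binomial counts. With a single binary covariate the maximum
#' likelihood fit is available in closed form (the fitted proportion of each
#' group is its pooled proportion), so the likelihood-ratio statistic against
#' the intercept-only null is computed directly and referred to chi-square
#' with 1 df; the statistic is identical to what IRLS fitting via `glm()`
#' yields, which the test suite verifies.
#'
#' @param test_counts,ctrl_counts two-column matrices (or vectors of length
#'   2) of per-replicate (n_meth, n_unmeth) counts.
#' @return list with `p`, likelihood-ratio `statistic`, and pooled group
#'   proportions `p_test`, `p_ctrl`.
#' @export
test_unit_logistic <- function(test_counts, ctrl_counts) {
  tc <- matrix(as.numeric(test_counts), ncol = 2)
  cc <- matrix(as.numeric(ctrl_counts), ncol = 2)
  Mt <- sum(tc[, 1]); Ut <- sum(tc[, 2])
  Mc <- sum(cc[, 1]); Uc <- sum(cc[, 2])
  if (Mt + Ut == 0 || Mc + Uc == 0) {
    warnf("test_unit_logistic: a group has zero coverage, p = 1")
    return(list(p = 1, statistic = 0, p_test = NA_real_, p_ctrl = NA_real_))
  }
  pt_ <- Mt / (Mt + Ut); pc_ <- Mc / (Mc + Uc)
  p0 <- (Mt + Mc) / (Mt + Ut + Mc + Uc)
  stat <- 2 * (binom_ll(Mt, Ut, pt_) + binom_ll(Mc, Uc, pc_) -
                 binom_ll(Mt + Mc, Ut + Uc, p0))
  stat <- max(stat, 0)
  list(p = pchisq(stat, df = 1, lower.tail = FALSE), statistic = stat,
       p_test = pt_, p_ctrl = pc_)
}

# vectorised LRT p-values over per-unit pooled group totals
lrt_p_vec <- function(Mt, Ut, Mc, Uc) {
  pt_ <- Mt / (Mt + Ut); pc_ <- Mc / (Mc + Uc)
  p0 <- (Mt + Mc) / (Mt + Ut + Mc + Uc)
  stat <- 2 * (binom_ll(Mt, Ut, pt_) + binom_ll(Mc, Uc, pc_) -
                 binom_ll(Mt + Mc, Ut + Uc, p0))
  pchisq(pmax(stat, 0), df = 1, lower.tail = FALSE)
}

# vectorised two-sided Fisher p-values over per-unit pooled group totals
fisher_p_vec <- function(Mt, Ut, Mc, Uc) {
  mapply(test_unit_fisher, Mt, Ut, Mc, Uc)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order and
#' capped at 1 (delegates to `stats::p.adjust(method = "BH")`).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
adjust_bh <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differential methylation
#'
#' A unit is hypomethylated when `diff <= -dm_min_diff` and `q <= dm_max_q`,
#' hypermethylated when `diff >= dm_min_diff` and `q <= dm_max_q`, otherwise
#' not significant. Boundaries are inclusive.
#'
#' @param diff methylation difference (test minus control, percentage
#'   points).
#' @param q BH-adjusted q-value.
#' @param config an [analysis_config].
#' @return character vector in `{"hypo", "hyper", "ns"}`.
#' @export
call_dm <- function(diff, q, config = analysis_config()) {
  out <- rep("ns", length(diff))
  sig <- !is.na(q) & q <= config$dm_max_q
  out[sig & diff <= -config$dm_min_diff] <- "hypo"
  out[sig & diff >= config$dm_min_diff] <- "hyper"
  out
}

#' Classify methylation state
#'
#' Partitions `[0, 100]` into unmethylated (`< state_low`), partial
#' (`state_low <= x < state_high`) and high (`>= state_high`). The boundary
#' at `state_high` belongs to the high class.
#'
#' @param percent methylation percentage(s) in `[0, 100]`.
#' @param config an [analysis_config].
#' @return character vector in `{"unmethylated", "partial", "high"}`.
#' @export
classify_state <- function(percent, config = analysis_config()) {
  if (any(is.na(percent)) || any(percent < 0 | percent > 100))
    stopf("percent must lie in [0, 100]")
  ifelse(percent >= config$state_high, "high",
         ifelse(percent >= config$state_low, "partial", "unmethylated"))
}

# shared site/tile DM engine: takes per-unit per-group pooled totals plus a
# table of all units with qualification flags
dm_test_units <- function(units, config, n_test, n_ctrl) {
  # units: data.table with unit, chrom, start, end, Mt, Ut, Mc, Uc, qualified
  method <- if (max(n_test, n_ctrl) >= 2L) "logistic" else "fisher"
  res <- copy(units)
  res[, `:=`(meth_test = NA_real_, meth_ctrl = NA_real_, diff = NA_real_,
             p = NA_real_, q = NA_real_, status = "unqualified")]
  qi <- which(res$qualified)
  if (length(qi)) {
    Mt <- res$Mt[qi]; Ut <- res$Ut[qi]; Mc <- res$Mc[qi]; Uc <- res$Uc[qi]
    mt_pct <- 100 * Mt / (Mt + Ut)
    mc_pct <- 100 * Mc / (Mc + Uc)
    pvals <- if (method == "logistic") lrt_p_vec(Mt, Ut, Mc, Uc)
             else fisher_p_vec(Mt, Ut, Mc, Uc)
    qvals <- adjust_bh(pvals)
    res[qi, `:=`(meth_test = mt_pct, meth_ctrl = mc_pct,
                 diff = mt_pct - mc_pct, p = pvals, q = qvals)]
    res[qi, status := call_dm(diff, q, config)]
  }
  res[, c("Mt", "Ut", "Mc", "Uc", "qualified") := NULL]
  setattr(res, "test_method", method)
  res[order(chrom, start, end)]
}

#' Site-level differential methylation
#'
#' Full site pipeline: qualification (coverage >= `min_site_cov` in every
#' sample), per-site test (binomial logistic LRT when either group has
#' replicates, Fisher exact for 1-vs-1), BH adjustment over qualified sites
#' only, and DM calling. Sites observed in any sample but not qualified are
#' reported with status `"unqualified"` and no test results.
#'
#' @param cmp a [comparison].
#' @param config an [analysis_config].
#' @return DM record `data.table` with columns `unit`, `chrom`, `pos`,
#'   `start`, `end` (0-based half-open), `meth_test`, `meth_ctrl`, `diff`,
#'   `p`, `q`, `status`; attribute `test_method` records the test used.
#' @export
run_site_dml <- function(cmp, config = analysis_config()) {
  long <- comparison_calls(cmp)
  n_samples <- length(cmp$test) + length(cmp$control)
  per_site <- long[, .(
    Mt = sum(n_meth[group == "test"]),
    Ut = sum(n_unmeth[group == "test"]),
    Mc = sum(n_meth[group == "control"]),
    Uc = sum(n_unmeth[group == "control"]),
    n_ok = sum(n_meth + n_unmeth >= config$min_site_cov)
  ), by = .(chrom, pos)]
  per_site[, qualified := n_ok == n_samples]
  per_site[, `:=`(unit = sprintf("%s:%d", chrom, pos),
                  start = pos - 1L, end = pos, n_ok = NULL)]
  out <- dm_test_units(per_site, config,
                       length(cmp$test), length(cmp$control))
  setcolorder(out, c("unit", "chrom", "pos", "start", "end"))
  out
}
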
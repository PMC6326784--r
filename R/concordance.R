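#' Extract Group A (hypomethylated) or Group B (unchanged) units
#'
#' Group A are the hypomethylated units of a comparison (difference <= -25
#' percentage points and q <= 0.01, boundaries inclusive); Group B are the
#' stringently unchanged units (|difference| < 5 and q > 0.1, both strict),
#' which excludes units with intermediate losses of 5-25%. The two groups
#' are disjoint by construction.
#'
#' @param records DM record `data.table` from [run_site_dml] or
#'   [run_tile_dml].
#' @param group `"A"` or `"B"`.
#' @param config an [analysis_config].
#' @return list of class `group_extract` with `group`, `units` (character
#'   ids) and `source` (the records' comparison label attribute, if any).
#' @export
extract_group <- function(records, group = c("A", "B"),
                          config = analysis_config()) {
  group <- match.arg(group)
  dt <- as.data.table(records)[status != "unqualified" & !is.na(q)]
  units <- if (group == "A") {
    dt[diff <= -config$dm_min_diff & q <= config$dm_max_q, unit]
  } else {
    dt[abs(diff) < config$unchanged_max_diff & q > config$unchanged_min_q,
       unit]
  }
  structure(list(group = group, units = units,
                 source = attr(records, "label") %||% NA_character_),
            class = "group_extract")
}

#' Units of an extract testable in every other comparison
#'
#' Restricts a group extract to the units that are qualified (testable) in
#' every listed other comparison, mirroring the "common tiles" restriction
#' used before computing concordance fractions.
#'
#' @param extract a `group_extract` from [extract_group].
#' @param other_records list of DM record tables from other comparisons
#'   (same tiling scheme).
#' @return character vector of unit ids.
#' @export
common_units <- function(extract, other_records) {
  units <- extract$units
  for (rec in other_records) {
    rec <- as.data.table(rec)
    ok <- rec[status != "unqualified", unit]
    units <- intersect(units, ok)
  }
  units
}

#' Concordance of a unit group in another comparison
#'
#' For a Group A extract, counts how many common units are called
#' hypomethylated in the other comparison; for Group B, how many satisfy the
#' unchanged criteria there (|difference| < 5 and q > 0.1). The reported
#' fraction rounds half-up to the nearest integer percent; the exact
#' fraction and the per-unit difference distribution are retained. The count
#' of merely non-significant units (`n_not_called`) is also reported.
#'
#' @param units character vector of common unit ids (see [common_units]).
#' @param other_records DM record table of the other comparison.
#' @param group `"A"` (count hypo calls) or `"B"` (count unchanged).
#' @param config an [analysis_config].
#' @return list of class `concordance_result`: `n_common`, `n_concordant`,
#'   `n_not_called`, `fraction_exact`, `fraction_reported`, `diffs`
#'   (named per-unit differences in the other comparison).
#' @export
concordance_fraction <- function(units, other_records, group = c("A", "B"),
                                 config = analysis_config()) {
  group <- match.arg(group)
  if (!length(units)) stopf("concordance_fraction: no common units")
  rec <- as.data.table(other_records)[unit %in% units]
  missing <- setdiff(units, rec$unit)
  if (length(missing))
    stopf("other comparison lacks %d of the common units", length(missing))
  concordant <- if (group == "A") {
    rec[, status == "hypo"]
  } else {
    rec[, !is.na(q) & abs(diff) < config$unchanged_max_diff &
          q > config$unchanged_min_q]
  }
  n_common <- length(units)
  n_conc <- sum(concordant)
  structure(list(
    group = group,
    n_common = n_common,
    n_concordant = n_conc,
    n_not_called = rec[, sum(status == "ns")],
    fraction_exact = count_percent(n_conc, n_common),
    fraction_reported = count_percent(n_conc, n_common, digits = 0),
    diffs = setNames(rec$diff, rec$unit)
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance> Group %s: %d of %d units concordant (%.1f%%, ~%d%%)\n",
              x$group, x$n_concordant, x$n_common, x$fraction_exact,
              x$fraction_reported))
  invisible(x)
}

#' Common and genotype-specific hypomethylated sites
#'
#' Builds the union of hypomethylated sites called in either of two
#' comparisons; union members with q <= 0.01 in both comparisons are common
#' sites, the remainder are partitioned by the comparison of origin.
#'
#' @param dm_a,dm_b site-level DM record tables of the two comparisons.
#' @param config an [analysis_config].
#' @return list with character unit-id vectors `common`, `a_only`, `b_only`.
#' @export
common_hypo_sites <- function(dm_a, dm_b, config = analysis_config()) {
  a <- as.data.table(dm_a); b <- as.data.table(dm_b)
  hypo_a <- a[status == "hypo", unit]
  hypo_b <- b[status == "hypo", unit]
  union_ab <- union(hypo_a, hypo_b)
  sig_a <- a[!is.na(q) & q <= config$dm_max_q, unit]
  sig_b <- b[!is.na(q) & q <= config$dm_max_q, unit]
  common <- intersect(union_ab, intersect(sig_a, sig_b))
  list(common = common,
       a_only = setdiff(intersect(union_ab, hypo_a), common),
       b_only = setdiff(setdiff(union_ab, hypo_a), common))
}

#' Export concordance results as a table
#'
#' @param results named list of `concordance_result` objects (names =
#'   other-comparison labels).
#' @param group_label label of the source group extraction.
#' @return `data.table` with one row per other comparison.
#' @export
concordance_table <- function(results, group_label = NA_character_) {
  rbindlist(lapply(names(results), function(lbl) {
    r <- results[[lbl]]
    data.table(group = r$group, source = group_label, other = lbl,
               n_common = r$n_common, n_concordant = r$n_concordant,
               n_not_called = r$n_not_called,
               fraction_exact = r$fraction_exact,
               fraction_reported = r$fraction_reported)
  }))
}
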
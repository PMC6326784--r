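#' Analysis configuration
#'
#' Collects every numeric threshold of the pipeline in one place so the
#' published cutoffs are visible and overridable together. Defaults are the
#' study settings: sites qualify at >= 20x coverage in every sample; 500-bp
#' tiles qualify with >= 3 CpGs at >= 10x in every sample; a unit is called
#' differentially methylated at |difference| >= 25 percentage points and
#' q <= 0.01 (boundaries inclusive); "true unchanged" units have
#' |difference| < 5 and q > 0.1 (strict); methylation states split at < 20%
#' (unmethylated), 20-80% (partial) and >= 80% (high).
#'
#' @param min_site_cov minimum per-sample read coverage for a CpG site to be
#'   testable (reads).
#' @param tile_width tile width in bp.
#' @param tile_min_cpgs minimum number of member CpGs (each covered
#'   `tile_min_cov`-fold in every sample) for a tile to be testable.
#' @param tile_min_cov per-sample coverage a member CpG needs to count toward
#'   `tile_min_cpgs`.
#' @param dm_min_diff minimum absolute methylation difference (percentage
#'   points) for a DM call.
#' @param dm_max_q maximum BH-adjusted q-value for a DM call.
#' @param unchanged_max_diff strict upper bound on |difference| for the
#'   unchanged (Group B) definition.
#' @param unchanged_min_q strict lower bound on q for the unchanged
#'   definition.
#' @param state_low,state_high state-class boundaries in percent: `< state_low`
#'   is unmethylated, `>= state_high` is high, in between is partial.
#' @param flank_upstream,flank_promoter,flank_tes,flank_downstream length-2
#'   integer vectors of signed distances (bp) from the TSS (upstream,
#'   promoter) or TES (tes, downstream) in transcription direction, half-open.
#' @param icr_merge_max_gap maximum gap (bp) between two same-locus ICRs for
#'   hypomethylation-supported merging.
#' @param icr_extend_max maximum distance (bp) an ICR boundary is extended
#'   toward outlying hypomethylated CpGs.
#' @param destrand if `TRUE`, merge the two strand calls of a CpG dyad
#'   (positions pos/pos+1) by summing counts at load time.
#' @param seed optional integer seed recorded into run manifests.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(min_site_cov = 20L,
                            tile_width = 500L,
                            tile_min_cpgs = 3L,
                            tile_min_cov = 10L,
                            dm_min_diff = 25,
                            dm_max_q = 0.01,
                            unchanged_max_diff = 5,
                            unchanged_min_q = 0.1,
                            state_low = 20,
                            state_high = 80,
                            flank_upstream = c(-5000L, -1000L),
                            flank_promoter = c(-1000L, 500L),
                            flank_tes = c(-500L, 1000L),
                            flank_downstream = c(1000L, 5000L),
                            icr_merge_max_gap = 500L,
                            icr_extend_max = 600L,
                            destrand = FALSE,
                            seed = NULL) {
  cfg <- list(
    min_site_cov = as.integer(min_site_cov),
    tile_width = as.integer(tile_width),
    tile_min_cpgs = as.integer(tile_min_cpgs),
    tile_min_cov = as.integer(tile_min_cov),
    dm_min_diff = dm_min_diff,
    dm_max_q = dm_max_q,
    unchanged_max_diff = unchanged_max_diff,
    unchanged_min_q = unchanged_min_q,
    state_low = state_low,
    state_high = state_high,
    flank_upstream = as.integer(flank_upstream),
    flank_promoter = as.integer(flank_promoter),
    flank_tes = as.integer(flank_tes),
    flank_downstream = as.integer(flank_downstream),
    icr_merge_max_gap = as.integer(icr_merge_max_gap),
    icr_extend_max = as.integer(icr_extend_max),
    destrand = isTRUE(destrand),
    seed = seed
  )
  with(cfg, {
    stopifnot(
      min_site_cov > 0, tile_width > 0, tile_min_cpgs > 0, tile_min_cov > 0,
      dm_min_diff > 0, dm_max_q > 0, unchanged_max_diff > 0,
      unchanged_min_q > 0, state_low < state_high,
      flank_upstream[1] < flank_upstream[2],
      flank_promoter[1] < flank_promoter[2],
      flank_tes[1] < flank_tes[2],
      flank_downstream[1] < flank_downstream[2],
      icr_merge_max_gap > 0, icr_extend_max > 0
    )
  })
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  site qualification : coverage >= %d in all samples\n", x$min_site_cov))
  cat(sprintf("  tile qualification : >= %d CpGs at >= %dx in all samples, %d-bp tiles\n",
              x$tile_min_cpgs, x$tile_min_cov, x$tile_width))
  cat(sprintf("  DM call            : |diff| >= %g%%, q <= %g\n", x$dm_min_diff, x$dm_max_q))
  cat(sprintf("  unchanged          : |diff| < %g%%, q > %g\n",
              x$unchanged_max_diff, x$unchanged_min_q))
  cat(sprintf("  states             : <%g%% / %g-%g%% / >=%g%%\n",
              x$state_low, x$state_low, x$state_high, x$state_high))
  invisible(x)
}
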
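#' Tile id of a 1-based site position
#'
#' Tiles are fixed, ungapped, non-overlapping windows `[k*w, (k+1)*w)`
#' (0-based half-open) anchored at the chromosome origin; a 1-based position
#' belongs to tile `floor((pos - 1) / w)`.
#'
#' @param pos 1-based position(s).
#' @param tile_width window width in bp.
#' @return 0-based tile start(s).
#' @export
tile_start_of <- function(pos, tile_width = 500L) {
  as.integer(floor((pos - 1) / tile_width) * tile_width)
}

#' Assign observed CpG sites to fixed tiles
#'
#' Only tiles containing at least one observed site (in any sample) are
#' materialised.
#'
#' @param call_sets list of [meth_call_set] (or a [comparison]).
#' @param tile_width window width in bp.
#' @return `data.table` mapping each observed site to its tile: columns
#'   `chrom`, `pos`, `tile_id`, `start`, `end`.
#' @export
assign_tiles <- function(call_sets, tile_width = 500L) {
  if (inherits(call_sets, "comparison"))
    call_sets <- c(call_sets$test, call_sets$control)
  sites <- unique(rbindlist(lapply(call_sets, function(s)
    s$calls[, .(chrom, pos)])))
  sites[, start := tile_start_of(pos, tile_width)]
  sites[, end := start + as.integer(tile_width)]
  sites[, tile_id := sprintf("%s:%d-%d", chrom, start, end)]
  setkey(sites, chrom, pos)
  sites[]
}

#' Qualify tiles for testing
#'
#' A tile qualifies when at least `tile_min_cpgs` of its member CpG sites
#' have coverage >= `tile_min_cov` in every sample of both groups. A site
#' counts toward the minimum only if it meets the coverage bar in all
#' samples (the per-site-in-all-samples reading, which keeps tiles
#' comparable across samples).
#'
#' @param site_tiles site-to-tile map from [assign_tiles].
#' @param cmp a [comparison].
#' @param config an [analysis_config].
#' @return `data.table` of qualified tiles (`tile_id`, `n_member_cpgs` =
#'   number of qualifying member sites).
#' @export
qualify_tiles <- function(site_tiles, cmp, config = analysis_config()) {
  long <- comparison_calls(cmp)
  n_samples <- length(cmp$test) + length(cmp$control)
  site_ok <- long[n_meth + n_unmeth >= config$tile_min_cov,
                  .(n_ok = .N), by = .(chrom, pos)][n_ok == n_samples]
  merged <- site_tiles[site_ok, on = c("chrom", "pos"), nomatch = NULL]
  merged[, .(n_member_cpgs = .N), by = tile_id][
    n_member_cpgs >= config$tile_min_cpgs]
}

#' Aggregate member-site counts per tile and sample
#'
#' Sums methylated and unmethylated counts over member sites per sample;
#' sites absent from a sample contribute nothing.
#'
#' @param site_tiles site-to-tile map from [assign_tiles].
#' @param call_sets list of [meth_call_set].
#' @return `data.table` with `tile_id`, `sample_id`, `n_meth`, `n_unmeth`.
#' @export
aggregate_tile_counts <- function(site_tiles, call_sets) {
  if (inherits(call_sets, "comparison"))
    call_sets <- c(call_sets$test, call_sets$control)
  long <- rbindlist(lapply(call_sets, function(s)
    cbind(s$calls, sample_id = s$sample_id)))
  merged <- long[site_tiles, on = c("chrom", "pos"), nomatch = NULL]
  merged[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
         by = .(tile_id, sample_id)]
}

#' Tile-level differential methylation
#'
#' Full tile pipeline: assign sites to fixed windows, qualify tiles, pool
#' member-site counts per group, test (same engine and thresholds as the
#' site level), BH over qualified tiles, and call. Unqualified tiles are
#' reported with status `"unqualified"`.
#'
#' @param cmp a [comparison].
#' @param config an [analysis_config].
#' @return DM record `data.table` with `unit` (= tile id), `chrom`, `start`,
#'   `end`, `n_member_cpgs`, `meth_test`, `meth_ctrl`, `diff`, `p`, `q`,
#'   `status`.
#' @export
run_tile_dml <- function(cmp, config = analysis_config()) {
  site_tiles <- assign_tiles(cmp, config$tile_width)
  qual <- qualify_tiles(site_tiles, cmp, config)
  long <- comparison_calls(cmp)
  merged <- long[site_tiles, on = c("chrom", "pos"), nomatch = NULL]
  per_tile <- merged[, .(
    Mt = sum(n_meth[group == "test"]),
    Ut = sum(n_unmeth[group == "test"]),
    Mc = sum(n_meth[group == "control"]),
    Uc = sum(n_unmeth[group == "control"])
  ), by = .(tile_id, chrom, start, end)]
  per_tile[, qualified := tile_id %in% qual$tile_id]
  per_tile[, unit := tile_id]
  out <- dm_test_units(per_tile, config,
                       length(cmp$test), length(cmp$control))
  out <- qual[out, on = "tile_id"]
  out[is.na(n_member_cpgs), n_member_cpgs := 0L]
  setcolorder(out, c("unit", "tile_id", "chrom", "start", "end",
                     "n_member_cpgs"))
  out[order(chrom, start)]
}
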
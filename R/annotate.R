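#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

location_priority <- c("promoter", "upstream", "tes", "downstream",
                       "exon", "intron", "intergenic")

#' Location categories in priority order
#'
#' The fixed resolution order when a site or tile overlaps several gene
#' features: promoter > upstream > TES > downstream > exon > intron >
#' intergenic.
#'
#' @return character vector of category names, highest priority first.
#' @export
location_categories <- function() location_priority

# flank interval in genome coordinates for a signed window around an anchor,
# oriented by strand; windows are half-open in transcription direction
oriented_window <- function(anchor, win, strand) {
  if (strand == "+") c(anchor + win[1], anchor + win[2])
  else c(anchor - win[2], anchor - win[1])
}

#' Derive strand-aware flank intervals of a gene
#'
#' For a plus-strand gene the TSS is `tx_start` and the TES is `tx_end`
#' (0-based); the promoter spans `[TSS - 1000, TSS + 500)`, upstream
#' `[TSS - 5000, TSS - 1000)`, the TES window `[TES - 500, TES + 1000)` and
#' downstream `[TES + 1000, TES + 5000)` by default. Minus-strand genes use
#' the mirror rule with TSS = `tx_end` and TES = `tx_start`. Intervals are
#' clipped at position 0. Exons are the annotated exon intervals; introns are
#' the gaps between consecutive exons.
#'
#' @param gene a one-row `gene_models` table (see [gene_model]).
#' @param config an [analysis_config] holding the flank windows.
#' @return `data.table` with columns `category`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
build_flanks <- function(gene, config = analysis_config()) {
  stopifnot(nrow(gene) == 1L)
  strand <- gene$strand
  tss <- if (strand == "+") gene$tx_start else gene$tx_end
  tes <- if (strand == "+") gene$tx_end else gene$tx_start
  iv <- list(
    promoter = oriented_window(tss, config$flank_promoter, strand),
    upstream = oriented_window(tss, config$flank_upstream, strand),
    tes = oriented_window(tes, config$flank_tes, strand),
    downstream = oriented_window(tes, config$flank_downstream, strand)
  )
  out <- rbindlist(lapply(names(iv), function(cat)
    data.table(category = cat, chrom = gene$chrom,
               start = iv[[cat]][1], end = iv[[cat]][2])))
  es <- gene$exon_starts[[1]]; ee <- gene$exon_ends[[1]]
  if (length(es))
    out <- rbind(out, data.table(category = "exon", chrom = gene$chrom,
                                 start = es, end = ee))
  if (length(es) > 1L)
    out <- rbind(out, data.table(category = "intron", chrom = gene$chrom,
                                 start = ee[-length(ee)], end = es[-1]))
  out[, start := pmax(as.integer(start), 0L)]
  out[, end := as.integer(end)]
  out <- out[start < end]
  out[]
}

# annotation index over all genes; one GRanges of category-labelled intervals
build_annotation_index <- function(genes, config = analysis_config()) {
  if (!nrow(genes)) {
    return(list(gr = GRanges(), category = character(0)))
  }
  flanks <- rbindlist(lapply(seq_len(nrow(genes)), function(i)
    build_flanks(genes[i], config)))
  gr <- GRanges(flanks$chrom,
                IRanges(start = flanks$start + 1L, end = flanks$end))
  list(gr = gr, category = flanks$category)
}

#' Assign genomic locations by priority
#'
#' Collects every feature category a query overlaps across all genes
#' (any-base overlap; a site is a width-1 query) and returns the
#' highest-priority one; queries overlapping nothing are intergenic.
#' Pooling categories across genes before resolution makes the result
#' independent of gene order.
#'
#' @param query `data.table`/data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), or with a 1-based `pos` column for sites.
#' @param genes `gene_models` table (see [read_genepred]).
#' @param config an [analysis_config].
#' @return character vector of categories, one per query row.
#' @export
assign_location <- function(query, genes, config = analysis_config()) {
  query <- as.data.table(query)
  if (!"start" %in% names(query) && "pos" %in% names(query))
    query[, `:=`(start = pos - 1L, end = pos)]
  if (!nrow(query)) return(character(0))
  out <- rep("intergenic", nrow(query))
  if (!nrow(genes)) return(out)
  idx <- build_annotation_index(genes, config)
  qgr <- GRanges(query$chrom,
                 IRanges(start = query$start + 1L, end = query$end))
  # queries on chromosomes without gene features are simply intergenic
  hits <- suppressWarnings(findOverlaps(qgr, idx$gr))
  if (length(hits)) {
    rank <- match(idx$category[subjectHits(hits)], location_priority)
    best <- tapply(rank, queryHits(hits), min)
    out[as.integer(names(best))] <- location_priority[best]
  }
  out
}

#' Overlap units with ICR regions
#'
#' Any-base overlap assignment of sites or tiles to named regions; a unit
#' overlapping several regions is assigned to the first by coordinate.
#'
#' @param units `data.table` with `chrom` and either 1-based `pos` or
#'   0-based half-open `start`/`end`.
#' @param icrs region `data.table` (`name`, `chrom`, `start`, `end`), e.g.
#'   from [read_bed].
#' @return character vector of region names, `NA` where no overlap.
#' @export
overlap_icr <- function(units, icrs) {
  units <- as.data.table(units)
  if (!"start" %in% names(units) && "pos" %in% names(units))
    units[, `:=`(start = pos - 1L, end = pos)]
  out <- rep(NA_character_, nrow(units))
  if (!nrow(units) || is.null(icrs) || !nrow(icrs)) return(out)
  icrs <- as.data.table(icrs)[order(chrom, start, end)]
  ugr <- GRanges(units$chrom, IRanges(start = units$start + 1L,
                                      end = units$end))
  igr <- GRanges(icrs$chrom, IRanges(start = icrs$start + 1L,
                                     end = icrs$end))
  hits <- suppressWarnings(findOverlaps(ugr, igr, select = "first"))
  out[!is.na(hits)] <- icrs$name[hits[!is.na(hits)]]
  out
}

#' Per-ICR, per-genotype pooled methylation
#'
#' Pools methylated/total read counts over the qualified CpG sites inside
#' each ICR, per genotype. A site is qualified when its coverage is at least
#' `min_site_cov` in every supplied sample. ICRs with no qualified site are
#' reported with `NA` percent (missing, not zero).
#'
#' @param call_sets list of [meth_call_set] (their `genotype` labels define
#'   the groups).
#' @param icrs region `data.table`.
#' @param config an [analysis_config].
#' @return `data.table` with `icr`, `genotype`, `n_sites`, `n_meth`,
#'   `n_total`, `percent` (one row per ICR x genotype; `NA` percent when no
#'   qualified site).
#' @export
icr_methylation_summary <- function(call_sets, icrs,
                                    config = analysis_config()) {
  long <- rbindlist(lapply(call_sets, function(s)
    cbind(s$calls, sample_id = s$sample_id, genotype = s$genotype)))
  n_samples <- length(call_sets)
  qual <- long[n_meth + n_unmeth >= config$min_site_cov,
               .(n_ok = .N), by = .(chrom, pos)][n_ok == n_samples,
                                                 .(chrom, pos)]
  qual[, icr := overlap_icr(qual, icrs)]
  qual <- qual[!is.na(icr)]
  genotypes <- unique(vapply(call_sets, `[[`, character(1), "genotype"))
  grid <- CJ(icr = icrs$name, genotype = genotypes, unique = TRUE)
  if (!nrow(qual)) {
    grid[, `:=`(n_sites = 0L, n_meth = 0L, n_total = 0L,
                percent = NA_real_)]
    return(grid[])
  }
  merged <- long[qual, on = c("chrom", "pos")]
  summ <- merged[, .(n_sites = uniqueN(paste(chrom, pos)),
                     n_meth = sum(n_meth),
                     n_total = sum(n_meth + n_unmeth)),
                 by = .(icr, genotype)]
  summ[, percent := 100 * n_meth / n_total]
  out <- summ[grid, on = c("icr", "genotype")]
  out[is.na(n_sites), `:=`(n_sites = 0L, n_meth = 0L, n_total = 0L)]
  out[order(icr, genotype)]
}

icr_name_prefix <- function(name) sub("[_.-][0-9]+$", "", name)

#' Refine ICR boundaries from hypomethylated CpGs
#'
#' Two data-driven boundary revisions, applied in order:
#' (a) two same-locus regions (names equal after stripping a trailing
#' numeric suffix) separated by at most `icr_merge_max_gap` bp are merged
#' into one continuous region when at least one hypomethylated CpG falls in
#' the gap; (b) a region boundary is extended outward to the farthest
#' hypomethylated CpG lying within `icr_extend_max` bp of that boundary.
#' The operation is idempotent: a second application changes nothing.
#'
#' @param icrs region `data.table` (`name`, `chrom`, `start`, `end`).
#' @param hypo_sites `data.table` of DM-called hypomethylated CpGs with
#'   `chrom` and 1-based `pos`.
#' @param config an [analysis_config].
#' @return list with `regions` (revised region table) and `log`
#'   (`data.table` of changes: action, name, detail distances).
#' @export
refine_icrs <- function(icrs, hypo_sites, config = analysis_config()) {
  regions <- as.data.table(icrs)[order(chrom, start, end)]
  hypo <- as.data.table(hypo_sites)
  if (nrow(hypo)) hypo[, pos0 := pos - 1L]
  changes <- list()

  # (a) merge same-locus neighbours across a hypomethylation-supported gap
  regions[, prefix := icr_name_prefix(name)]
  repeat {
    merged_any <- FALSE
    setorder(regions, chrom, start, end)
    for (i in seq_len(nrow(regions) - 1L)) {
      a <- regions[i]; b <- regions[i + 1L]
      if (a$chrom != b$chrom || a$prefix != b$prefix) next
      gap <- b$start - a$end
      if (gap < 0L || gap > config$icr_merge_max_gap) next
      n_gap <- if (nrow(hypo))
        hypo[chrom == a$chrom & pos0 >= a$end & pos0 < b$start, .N] else 0L
      if (n_gap < 1L) next
      changes[[length(changes) + 1L]] <- data.table(
        action = "merge", name = a$prefix,
        detail = sprintf("merged %s and %s across %d-bp gap (%d hypo CpGs in gap)",
                         a$name, b$name, gap, n_gap))
      regions <- rbind(
        regions[-c(i, i + 1L)],
        data.table(name = a$prefix, chrom = a$chrom, start = a$start,
                   end = b$end, prefix = a$prefix))
      merged_any <- TRUE
      break
    }
    if (!merged_any) break
  }

  # (b) extend boundaries to the farthest nearby hypomethylated CpG
  if (nrow(hypo)) {
    for (i in seq_len(nrow(regions))) {
      r <- regions[i]
      left <- hypo[chrom == r$chrom & pos0 >= r$start - config$icr_extend_max &
                     pos0 < r$start]
      if (nrow(left)) {
        d <- r$start - min(left$pos0)
        regions[i, start := start - d]
        changes[[length(changes) + 1L]] <- data.table(
          action = "extend_start", name = r$name,
          detail = sprintf("start extended by %d bp (%d hypo CpGs 1-%d bp upstream)",
                           d, nrow(left), d))
      }
      right <- hypo[chrom == r$chrom & pos0 >= r$end &
                      pos0 < r$end + config$icr_extend_max]
      if (nrow(right)) {
        d <- max(right$pos0) - r$end + 1L
        regions[i, end := end + d]
        changes[[length(changes) + 1L]] <- data.table(
          action = "extend_end", name = r$name,
          detail = sprintf("end extended by %d bp (%d hypo CpGs 1-%d bp downstream)",
                           d, nrow(right), d))
      }
    }
  }
  regions[, prefix := NULL]
  setorder(regions, chrom, start, end)
  log <- if (length(changes)) rbindlist(changes)
         else data.table(action = character(), name = character(),
                         detail = character())
  list(regions = regions[], log = log)
}
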
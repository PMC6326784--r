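library(data.table)

# quick call-set builder from parallel vectors
calls_of <- function(pos, n_meth, n_unmeth, chrom = "chr1") {
  data.table(chrom = chrom, pos = as.integer(pos),
             n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth))
}

set_of <- function(id, genotype, pos, n_meth, n_unmeth, chrom = "chr1") {
  meth_call_set(id, genotype, calls_of(pos, n_meth, n_unmeth, chrom))
}

# minimal DM record table for concordance tests
dm_records_of <- function(unit, diff, q, status = NULL, config = analysis_config()) {
  st <- status %||% call_dm(diff, q, config)
  data.table(unit = unit, chrom = "chr1",
             start = seq_along(unit) * 500L, end = seq_along(unit) * 500L + 500L,
             meth_test = NA_real_, meth_ctrl = NA_real_,
             diff = diff, p = q, q = q, status = st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small synthetic genome used throughout the suite; ~5000 CpGs keeps the
# full pipeline runs fast while leaving >= 50 ICR CpGs for the ICR checks
small_spec <- function(...) {
  synthetic_genome_spec(chrom_lengths = c(chr1 = 400000L),
                        n_genes = 10L, gene_size = c(3000L, 20000L),
                        n_icrs = 6L, icr_size = 2000L,
                        target_tile_fraction = 0.05, ...)
}

# one shared small study per session (deterministic; seed fixed up front)
get_small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_study(small_spec(), seed = 20180913L)
    cache
  }
})

get_small_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_study(get_small_study(), quiet = TRUE)
    cache
  }
})

# independent brute-force oracles -------------------------------------------

# BH step-up by literal min-over-suffix on the sorted p-values
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(n)
  for (i in seq_len(n)) qs[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- qs
  out
}

# two-sided Fisher by exhaustive enumeration of all 2x2 tables with the
# observed margins, probabilities from binomial coefficients
fisher_brute <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# plain-arithmetic location assignment for one site/interval against genes,
# independent of the GenomicRanges code path
locate_brute <- function(q_start, q_end, q_chrom, genes, config = analysis_config()) {
  cats <- character(0)
  overlaps <- function(s, e) s < q_end && e > q_start
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    if (g$chrom != q_chrom) next
    if (g$strand == "+") {
      tss <- g$tx_start; tes <- g$tx_end
      win <- list(
        promoter = c(tss + config$flank_promoter[1], tss + config$flank_promoter[2]),
        upstream = c(tss + config$flank_upstream[1], tss + config$flank_upstream[2]),
        tes = c(tes + config$flank_tes[1], tes + config$flank_tes[2]),
        downstream = c(tes + config$flank_downstream[1], tes + config$flank_downstream[2]))
    } else {
      tss <- g$tx_end; tes <- g$tx_start
      win <- list(
        promoter = c(tss - config$flank_promoter[2], tss - config$flank_promoter[1]),
        upstream = c(tss - config$flank_upstream[2], tss - config$flank_upstream[1]),
        tes = c(tes - config$flank_tes[2], tes - config$flank_tes[1]),
        downstream = c(tes - config$flank_downstream[2], tes - config$flank_downstream[1]))
    }
    for (cat in names(win))
      if (overlaps(max(win[[cat]][1], 0), win[[cat]][2])) cats <- c(cats, cat)
    es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
    for (j in seq_along(es)) if (overlaps(es[j], ee[j])) cats <- c(cats, "exon")
    if (length(es) > 1)
      for (j in seq_len(length(es) - 1))
        if (overlaps(ee[j], es[j + 1])) cats <- c(cats, "intron")
  }
  if (!length(cats)) return("intergenic")
  priority <- location_categories()
  priority[min(match(cats, priority))]
}
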
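test_that("flank intervals follow the strand-oriented windows", {
  g <- gene_model("g", "chr1", "+", 10000L, 20000L)
  fl <- build_flanks(g)
  expect_equal(fl[category == "promoter", .(start, end)],
               data.table(start = 9000L, end = 10500L))
  expect_equal(fl[category == "upstream", .(start, end)],
               data.table(start = 5000L, end = 9000L))
  expect_equal(fl[category == "tes", .(start, end)],
               data.table(start = 19500L, end = 21000L))
  expect_equal(fl[category == "downstream", .(start, end)],
               data.table(start = 21000L, end = 25000L))
  # minus strand mirrors around TSS = tx_end
  gm <- gene_model("g", "chr1", "-", 2000L, 10000L)
  flm <- build_flanks(gm)
  expect_equal(flm[category == "promoter", .(start, end)],
               data.table(start = 9500L, end = 11000L))
  expect_equal(flm[category == "upstream", .(start, end)],
               data.table(start = 11000L, end = 15000L))
  # single exon -> no introns; intervals clipped at 0
  expect_false("intron" %in% fl$category)
  g0 <- gene_model("g0", "chr1", "+", 500L, 3000L)
  fl0 <- build_flanks(g0)
  expect_equal(fl0[category == "upstream", .N], 0L)  # fully left of origin
  expect_equal(fl0[category == "promoter", start], 0L)
})

test_that("location assignment resolves by the fixed priority order", {
  # promoter of A beats intron of B
  a <- gene_model("A", "chr1", "+", 10000L, 20000L)
  b <- gene_model("B", "chr1", "+", 5000L, 30000L,
                  exon_starts = c(5000L, 29000L),
                  exon_ends = c(6000L, 30000L))
  genes <- rbind(a, b)
  class(genes) <- class(a)
  expect_equal(assign_location(data.table(chrom = "chr1", pos = 9500L), genes),
               "promoter")
  # 3 kb upstream of the only gene
  expect_equal(assign_location(data.table(chrom = "chr1", pos = 7001L), a),
               "upstream")
  # gene-free chromosome
  expect_equal(assign_location(data.table(chrom = "chrX", pos = 9500L), genes),
               "intergenic")
  # gene order never matters
  genes2 <- rbind(b, a); class(genes2) <- class(a)
  pts <- data.table(chrom = "chr1", pos = seq(4000L, 32000L, by = 371L))
  expect_equal(assign_location(pts, genes), assign_location(pts, genes2))
})

test_that("location assignment equals the all-pairs brute-force scan", {
  set.seed(12)
  genes <- do.call(rbind, lapply(1:20, function(i) {
    start <- sample(5e4, 1) + 10000L
    len <- sample(2000:20000, 1)
    n_ex <- sample(1:4, 1)
    cuts <- sort(sample(seq(start + 1, start + len - 1), 2 * n_ex - 2))
    bounds <- c(start, cuts, start + len)
    gene_model(sprintf("g%d", i), sample(c("chr1", "chr2"), 1),
               sample(c("+", "-"), 1), start, start + len,
               exon_starts = bounds[seq(1, length(bounds), 2)],
               exon_ends = bounds[seq(2, length(bounds), 2)])
  }))
  class(genes) <- c("gene_models", "data.table", "data.frame")
  sites <- data.table(chrom = sample(c("chr1", "chr2"), 1000, TRUE),
                      pos = sample.int(9e4, 1000))
  got <- assign_location(sites, genes)
  want <- vapply(seq_len(nrow(sites)), function(i)
    locate_brute(sites$pos[i] - 1L, sites$pos[i], sites$chrom[i], genes),
    character(1))
  expect_equal(got, want)
})

test_that("flank assignment is mirror-symmetric under strand reflection", {
  cfg <- analysis_config()
  g_plus <- gene_model("g", "chr1", "+", 50000L, 70000L,
                       exon_starts = c(50000L, 60000L),
                       exon_ends = c(55000L, 70000L))
  refl <- 200000L  # reflect through this point: x -> refl - x
  g_minus <- gene_model("g", "chr1", "-", refl - 70000L, refl - 50000L,
                        exon_starts = refl - c(70000L, 55000L),
                        exon_ends = refl - c(60000L, 50000L))
  pts <- seq(44000L, 76000L, by = 997L)
  for (p in pts) {
    cat_p <- assign_location(data.table(chrom = "chr1", pos = p), g_plus, cfg)
    # reflected width-1 query [p-1, p) maps to [refl - p, refl - p + 1)
    cat_m <- assign_location(data.table(chrom = "chr1", pos = refl - p + 1L),
                             g_minus, cfg)
    expect_equal(cat_p, cat_m)
  }
})

test_that("ICR overlap respects the 0-based half-open boundary", {
  icrs <- data.table(name = "ZAC1", chrom = "chr7", start = 1000L,
                     end = 2000L)
  expect_equal(overlap_icr(data.table(chrom = "chr7", pos = 1500L), icrs),
               "ZAC1")
  expect_equal(overlap_icr(data.table(chrom = "chr7", pos = 1000L), icrs),
               NA_character_)  # 0-based 999 is left of the region
  expect_equal(overlap_icr(data.table(chrom = "chr7", pos = 2000L), icrs),
               "ZAC1")
  expect_equal(overlap_icr(data.table(chrom = "chr7", pos = 1500L),
                           icrs[0]), NA_character_)
})

test_that("ICR summaries pool qualified sites and report missing ICRs as NA", {
  icrs <- data.table(name = c("I1", "I2"), chrom = "chr1",
                     start = c(1000L, 9000L), end = c(2000L, 9500L))
  # monoallelic ICR sites at ~50%: 15 of 30 reads methylated
  pos <- seq(1101L, 1901L, by = 100L)
  sets <- lapply(1:3, function(i)
    set_of(sprintf("wt%d", i), "WT", pos, 15, 15))
  summ <- icr_methylation_summary(sets, icrs)
  expect_equal(summ[icr == "I1" & genotype == "WT", percent], 50)
  expect_true(is.na(summ[icr == "I2" & genotype == "WT", percent]))
  # all-unmethylated reads -> exactly 0
  sets0 <- lapply(1:3, function(i)
    set_of(sprintf("ko%d", i), "mKO", pos, 0, 30))
  expect_equal(icr_methylation_summary(sets0, icrs)[icr == "I1", percent], 0)
})

test_that("ICR refinement merges across supported gaps and extends to outliers", {
  cfg <- analysis_config()
  icrs <- data.table(name = c("ZAC1_1", "ZAC1_2", "GRB10"),
                     chrom = c("chr10", "chr10", "chr11"),
                     start = c(1000L, 3346L, 5000L),
                     end = c(3000L, 5000L, 8000L))
  # 346-bp gap between the ZAC1 pair holds hypomethylated CpGs;
  # GRB10 has hypo CpGs 13-549 bp downstream of its end
  hypo <- data.table(chrom = c(rep("chr10", 5), "chr11", "chr11"),
                     pos = c(3100L, 3150L, 3200L, 3250L, 3300L,
                             8000L + 13L, 8000L + 549L))
  ref <- refine_icrs(icrs, hypo, cfg)
  zac <- ref$regions[name == "ZAC1"]
  expect_equal(nrow(zac), 1L)
  expect_equal(c(zac$start, zac$end), c(1000L, 5000L))
  grb <- ref$regions[name == "GRB10"]
  expect_equal(grb$end, 8000L + 549L)
  expect_equal(grb$start, 5000L)
  expect_setequal(ref$log$action, c("merge", "extend_end"))

  # no hypo CpGs outside any region -> identity
  inside <- data.table(chrom = "chr11", pos = 6000L)
  same <- refine_icrs(icrs, inside, cfg)
  expect_equal(same$regions[order(name)],
               icrs[order(name)])
  expect_equal(nrow(same$log), 0L)

  # idempotence
  again <- refine_icrs(ref$regions, hypo, cfg)
  expect_equal(again$regions, ref$regions)
  expect_equal(nrow(again$log), 0L)
})
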
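test_that("the simulated methylome is a pure function of the seed", {
  a <- simulate_methylome(small_spec(), seed = 99)
  b <- simulate_methylome(small_spec(), seed = 99)
  expect_equal(a$truth, b$truth)
  expect_equal(a$icrs, b$icrs)
  expect_equal(a$target_tiles, b$target_tiles)
  c_ <- simulate_methylome(small_spec(), seed = 100)
  expect_false(isTRUE(all.equal(a$truth$level, c_$truth$level)))
})

test_that("background site levels are bimodal and ICR sites average 0.5", {
  sim <- simulate_methylome(small_spec(), seed = 21)
  bg <- sim$truth[class_ == "none"]
  expect_gt(mean(bg$level < 0.2 | bg$level > 0.8), 0.75)
  icr <- sim$truth[class_ == "icr"]
  expect_gte(nrow(icr), 50)
  expect_equal(unique((icr$allele1 + icr$allele2) / 2), 0.5)
  # ICRs and genes live within chromosome bounds; targets disjoint from ICRs
  expect_true(all(sim$icrs$end <= small_spec()$chrom_lengths["chr1"]))
  icr_tiles <- unique(sprintf("%s:%d-%d", icr$chrom, tile_start_of(icr$pos),
                              tile_start_of(icr$pos) + 500L))
  expect_length(intersect(sim$target_tiles, icr_tiles), 0)
})

test_that("genotype effects follow the planted rules", {
  sim <- simulate_methylome(small_spec(), seed = 22)
  wt <- apply_genotype(sim, "WT")
  expect_equal(wt$truth, sim$truth)
  ko <- apply_genotype(sim, "KO", effect_delta = 0.30)
  # ICR alleles untouched in KO
  expect_equal(ko$truth[class_ == "icr", .(allele1, allele2)],
               sim$truth[class_ == "icr", .(allele1, allele2)])
  # target levels reduced by delta, floored at 0
  expect_equal(ko$truth[class_ == "target", level],
               pmax(sim$truth[class_ == "target", level] - 0.30, 0))
  mzko <- apply_genotype(sim, "mzKO", effect_delta = 0.30)
  expect_true(all(mzko$truth[class_ == "icr", allele1 == 0 & allele2 == 0]))
  expect_equal(mzko$truth[class_ == "target", level],
               ko$truth[class_ == "target", level])
  mko <- apply_genotype(sim, "mKO")
  expect_equal(mko$truth[class_ == "none", level],
               sim$truth[class_ == "none", level])
  expect_error(apply_genotype(sim, "dko"), "unknown genotype")
})

test_that("emitted counts are deterministic and moment-faithful", {
  out <- withr::local_tempdir()
  sim <- simulate_methylome(small_spec(), seed = 23)
  e1 <- emit_counts(sim, n_replicates = 2, seed = 7, out_dir = out)
  e2 <- emit_counts(sim, n_replicates = 2, seed = 7,
                    out_dir = file.path(out, "b"))
  expect_identical(readLines(e1$files[1]),
                   readLines(e2$files[1]))  # byte-identical by seed
  expect_identical(e1$conversion$n_unconverted, e2$conversion$n_unconverted)
  # observed percent at a fixed high level matches the conversion-adjusted
  # closed form 100 * (0.95 + 0.05 * 0.005) = 95.0025
  n <- 20000L
  flat <- sim
  flat$truth <- data.table(chrom = "chr1", pos = seq_len(n) * 10L,
                           class_ = "none", icr_name = NA_character_,
                           level = 0.95, allele1 = NA_real_,
                           allele2 = NA_real_, cov_factor = 1)
  em <- emit_counts(flat, n_replicates = 1, mean_cov = 30,
                    conv_fail = 0.005, seed = 8)
  obs <- mean(call_percents(em$call_sets[[1]]))
  expect_lt(abs(obs - 95.0025), 0.5)
  # conversion QC pool reflects the failure probability
  conv <- em$conversion
  rate <- conversion_rate(conv$n_converted, conv$n_unconverted)
  expect_equal(rate$rate, 99.5, tolerance = 0.2)
})

test_that("ICR reads are sampled allele-first around a genuine 50%", {
  sim <- simulate_methylome(small_spec(), seed = 24)
  em <- emit_counts(sim, n_replicates = 3, mean_cov = 30, seed = 9)
  long <- data.table::rbindlist(lapply(em$call_sets, function(s) s$calls))
  icr_pos <- sim$truth[class_ == "icr", .(chrom, pos)]
  icr_calls <- long[icr_pos, on = c("chrom", "pos")]
  pct <- 100 * sum(icr_calls$n_meth) /
    sum(icr_calls$n_meth + icr_calls$n_unmeth)
  expect_lt(abs(pct - 50), 3)
})

test_that("empirical site means converge to truth at deep coverage", {
  spec <- synthetic_genome_spec(chrom_lengths = c(chr1 = 50000L),
                                n_genes = 2L, gene_size = c(3000L, 8000L),
                                n_icrs = 1L, icr_size = 1000L)
  sim <- simulate_methylome(spec, seed = 25)
  em <- emit_counts(sim, n_replicates = 3, mean_cov = 300, conv_fail = 0,
                    seed = 10)
  long <- data.table::rbindlist(lapply(em$call_sets, function(s) s$calls))
  pooled <- long[, .(obs = sum(n_meth) / sum(n_meth + n_unmeth)),
                 by = .(chrom, pos)]
  merged <- pooled[sim$truth, on = c("chrom", "pos")]
  non_icr <- merged[class_ != "icr"]
  expect_lt(mean(abs(non_icr$obs - non_icr$level)), 0.01)
})

test_that("a full study is reproducible and writes the expected artifacts", {
  out <- withr::local_tempdir()
  study <- make_study(small_spec(), seed = 31, out_dir = out)
  expect_equal(length(unlist(study$call_sets, recursive = FALSE)), 12L)
  expect_true(all(file.exists(file.path(out, c("icrs.bed", "genes.genePred",
                                               "truth_wt.tsv",
                                               "manifest.json")))))
  expect_equal(length(list.files(out, pattern = "\\.cov$")), 12L)
  # all emitted sites lie at simulated CpG positions
  wt1 <- study$call_sets$WT[[1]]
  expect_true(all(paste(wt1$calls$chrom, wt1$calls$pos) %in%
                    paste(study$genome$truth$chrom, study$genome$truth$pos)))
  # identical seed reproduces the dataset bit-exactly
  study2 <- make_study(small_spec(), seed = 31)
  expect_equal(study$call_sets$mzKO[[3]]$calls,
               study2$call_sets$mzKO[[3]]$calls)
  expect_identical(study$conversion, study2$conversion)
  # per-genotype replicate override: the 2-replicate zygotic-KO scenario
  study3 <- make_study(small_spec(), seed = 31,
                       n_replicates = c(WT = 3, mKO = 3, KO = 2, mzKO = 3))
  expect_length(study3$call_sets$KO, 2L)
  expect_length(study3$call_sets$WT, 3L)
})
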
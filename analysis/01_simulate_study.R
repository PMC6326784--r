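#!/usr/bin/env Rscript
# Simulate the full RRBS study: one shared methylome, four genotypes
# (WT, mKO, KO, mzKO), three replicates each, written as Bismark coverage
# files plus ICR BED, genePred gene models, ground truth and a manifest.
# Heavy per-sample files go to scratch/; small overview tables to results/.

suppressMessages(library(methdiffr))
suppressMessages(library(data.table))

seed <- 20180947L
study_dir <- "scratch/study"
dir.create("results", showWarnings = FALSE)

study <- make_study(seed = seed, out_dir = study_dir)
print(study)

# samples sheet driving the downstream scripts
samples <- rbindlist(lapply(names(study$call_sets), function(g)
  data.table(sample_id = vapply(study$call_sets[[g]], `[[`, "", "sample_id"),
             genotype = g,
             path = file.path(study_dir,
                              sprintf("%s.cov", vapply(study$call_sets[[g]],
                                                       `[[`, "", "sample_id"))))))
fwrite(samples, file.path(study_dir, "samples.tsv"), sep = "\t")

truth <- study$genome$truth
overview <- data.table(
  n_cpgs = nrow(truth),
  n_icr_cpgs = truth[class_ == "icr", .N],
  n_target_tiles = length(study$target_tiles),
  frac_bimodal = truth[class_ == "none", mean(level < 0.2 | level > 0.8)],
  seed = seed
)
fwrite(overview, "results/study_overview.tsv", sep = "\t")
message(sprintf("simulated %d CpGs (%d in ICRs), %d target tiles; %.0f%% of background sites bimodal",
                overview$n_cpgs, overview$n_icr_cpgs, overview$n_target_tiles,
                100 * overview$frac_bimodal))
message("coverage files and truth written under ", study_dir)
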
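#!/usr/bin/env Rscript
# Targeted quantification: clone-based bisulfite percentages for small
# amplified regions, bisulfite conversion QC from the synthetic non-CpG
# cytosine pools, and protein half-life estimation from cycloheximide-chase
# densitometry curves.

suppressMessages(library(methdiffr))
suppressMessages(library(data.table))

study_dir <- "scratch/study"
dir.create("results", showWarnings = FALSE)

# clone-based region quantification: a hypomethylated promoter-like region
# (few methylated calls) next to a methylated one, 10 clones x 8 CpGs
set.seed(11)
lowm <- matrix(rbinom(80, 1, 0.08), nrow = 10)
highm <- matrix(rbinom(80, 1, 0.85), nrow = 10)
highm[sample(80, 6)] <- NA  # a few unreadable calls
clone_tab <- data.table(
  region = c("promoter_like", "body_like"),
  n_clones = 10L,
  n_calls = c(sum(!is.na(lowm)), sum(!is.na(highm))),
  percent = c(clone_region_percent(lowm), clone_region_percent(highm)))

# conversion QC over every emitted sample
conv <- rbindlist(lapply(list.files(study_dir, pattern = "_conversion.tsv$",
                                    full.names = TRUE), fread))
qc <- conv[, {
  r <- conversion_rate(n_converted, n_unconverted)
  .(rate = r$rate, pass = r$pass)
}, by = sample_id]
fwrite(qc, "results/conversion_qc.tsv", sep = "\t")
message(sprintf("conversion QC: %d/%d samples above 99%% (mean %.2f%%)",
                sum(qc$pass), nrow(qc), mean(qc$rate)))

# half-life from cycloheximide-chase curves: the KO-like series decays with
# t1/2 = 6 h; the WT-like series is still near its start after 12 h
curves <- list(
  KO_like = list(t = c(0, 3, 6, 12), y = c(100, 70.71, 50, 25)),
  WT_like = list(t = c(0, 3, 6, 12), y = c(100, 97, 94, 88)))
hl_rows <- rbindlist(lapply(names(curves), function(nm) {
  res <- half_life(curves[[nm]]$t, curves[[nm]]$y)
  data.table(curve = nm, half_life_h = res$half_life,
             r_squared = res$r_squared)
}))
fwrite(cbind(clone_tab[, .(region, n_clones, n_calls, percent)]),
       "results/clone_percents.tsv", sep = "\t")
fwrite(hl_rows, "results/half_life.tsv", sep = "\t")
for (i in seq_len(nrow(hl_rows)))
  message(sprintf("%s: t1/2 = %.2f h (R^2 = %.3f)", hl_rows$curve[i],
                  hl_rows$half_life_h[i], hl_rows$r_squared[i]))
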
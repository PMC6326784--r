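#!/usr/bin/env Rscript
# Cross-genotype concordance: extract the hypomethylated (Group A) and
# stringently unchanged (Group B) tiles of the zygotic KO and quantify how
# they behave in the mzKO (shares the planted DNMT3A-target losses) and the
# mKO (does not) comparisons; also the common-hypomethylated-site split
# between KO and mzKO at site resolution.

suppressMessages(library(methdiffr))
suppressMessages(library(data.table))

dml_dir <- "scratch/dml"
cfg <- analysis_config()

tile <- lapply(c(KO_vs_WT = "KO_vs_WT", mzKO_vs_WT = "mzKO_vs_WT",
                 mKO_vs_WT = "mKO_vs_WT"), function(lbl)
  read_dm_table(file.path(dml_dir, sprintf("tile_%s.tsv", lbl))))

rows <- list()
for (grp in c("A", "B")) {
  ext <- extract_group(tile$KO_vs_WT, grp, cfg)
  units <- common_units(ext, tile[c("mzKO_vs_WT", "mKO_vs_WT")])
  res <- lapply(tile[c("mzKO_vs_WT", "mKO_vs_WT")], function(rec)
    concordance_fraction(units, rec, grp, cfg))
  rows[[grp]] <- concordance_table(res, "KO_vs_WT")
  for (lbl in names(res))
    message(sprintf("Group %s in %s: %d of %d (~%d%%)", grp, lbl,
                    res[[lbl]]$n_concordant, res[[lbl]]$n_common,
                    res[[lbl]]$fraction_reported))
  # per-unit differences for violin-style plotting
  diffs <- rbindlist(lapply(names(res), function(lbl)
    data.table(group = grp, other = lbl, unit = names(res[[lbl]]$diffs),
               diff = res[[lbl]]$diffs)))
  fwrite(diffs, sprintf("scratch/dml/group%s_diffs.tsv", grp), sep = "\t")
}
fwrite(rbindlist(rows), "results/concordance.tsv", sep = "\t")

site_ko <- read_dm_table(file.path(dml_dir, "site_KO_vs_WT.tsv"))
site_mzko <- read_dm_table(file.path(dml_dir, "site_mzKO_vs_WT.tsv"))
cs <- common_hypo_sites(site_ko, site_mzko, cfg)
fwrite(data.table(set = c("common", "KO_only", "mzKO_only"),
                  n = c(length(cs$common), length(cs$a_only),
                        length(cs$b_only))),
       "results/common_hypo_sites.tsv", sep = "\t")
message(sprintf("hypomethylated-site union split: %d common, %d KO-only, %d mzKO-only",
                length(cs$common), length(cs$a_only), length(cs$b_only)))
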
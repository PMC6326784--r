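#' Build the standard genotype comparisons of a study
#'
#' Comparison labels follow the "test_vs_control" convention; the
#' methylation difference is always test minus control.
#'
#' @param study a `synthetic_study` (or any list with a `call_sets` element
#'   keyed by genotype).
#' @param control control genotype (default "WT").
#' @param tests test genotypes (default every other genotype present).
#' @return named list of [comparison] objects.
#' @export
study_comparisons <- function(study, control = "WT",
                              tests = setdiff(names(study$call_sets),
                                              control)) {
  stopifnot(control %in% names(study$call_sets))
  out <- lapply(tests, function(g)
    comparison(study$call_sets[[g]], study$call_sets[[control]],
               label = sprintf("%s_vs_%s", g, control)))
  setNames(out, vapply(out, `[[`, character(1), "label"))
}

#' Run the full analysis over a synthetic study
#'
#' One-shot orchestration of every stage, mirroring the published analysis
#' plan on generated data: site-level DM for each mutant genotype against
#' WT; tile-level DM at identical thresholds; priority-ordered genomic
#' annotation and ICR overlap of the tile records; per-ICR methylation
#' summaries; ICR boundary refinement from the maternal-KO hypomethylated
#' sites; and cross-genotype concordance of the zygotic-KO Group A
#' (hypomethylated) and Group B (unchanged) tiles in the other two
#' comparisons. When `out_dir` is given, every stage writes its TSV and a
#' JSON run manifest records parameters, thresholds and output paths.
#'
#' @param study a `synthetic_study` from [make_study].
#' @param config an [analysis_config].
#' @param out_dir optional output directory for stage TSVs and the manifest.
#' @param quiet suppress per-stage messages.
#' @return list of class `study_results`: `site_dml`, `tile_dml` (named by
#'   comparison), `icr_summary`, `icr_refined`, `concordance` (table),
#'   `common_sites`, `summary` (per-comparison call counts), `manifest`.
#' @export
run_study <- function(study, config = analysis_config(), out_dir = NULL,
                      quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cmps <- study_comparisons(study)
  say("thresholds: |diff| >= %g, q <= %g; site cov >= %d; tile: >= %d CpGs at >= %dx",
      config$dm_min_diff, config$dm_max_q, config$min_site_cov,
      config$tile_min_cpgs, config$tile_min_cov)

  site_dml <- list(); tile_dml <- list()
  for (lbl in names(cmps)) {
    site_dml[[lbl]] <- run_site_dml(cmps[[lbl]], config)
    setattr(site_dml[[lbl]], "label", lbl)
    tile_dml[[lbl]] <- run_tile_dml(cmps[[lbl]], config)
    setattr(tile_dml[[lbl]], "label", lbl)
    say("%s: %d/%d sites qualified (%d hypo, %d hyper); %d/%d tiles qualified (%d hypo, %d hyper)",
        lbl,
        site_dml[[lbl]][status != "unqualified", .N], nrow(site_dml[[lbl]]),
        site_dml[[lbl]][status == "hypo", .N],
        site_dml[[lbl]][status == "hyper", .N],
        tile_dml[[lbl]][status != "unqualified", .N], nrow(tile_dml[[lbl]]),
        tile_dml[[lbl]][status == "hypo", .N],
        tile_dml[[lbl]][status == "hyper", .N])
  }

  # annotation of tile records: location by priority, ICR by overlap
  for (lbl in names(tile_dml)) {
    tile_dml[[lbl]][, location := assign_location(.SD, study$genes, config),
                    .SDcols = c("chrom", "start", "end")]
    tile_dml[[lbl]][, icr := overlap_icr(.SD, study$icrs),
                    .SDcols = c("chrom", "start", "end")]
  }
  for (lbl in names(site_dml)) {
    site_dml[[lbl]][, icr := overlap_icr(.SD, study$icrs),
                    .SDcols = c("chrom", "pos")]
  }

  # per-ICR methylation by genotype over all samples
  icr_summary <- icr_methylation_summary(unlist(study$call_sets,
                                                recursive = FALSE),
                                         study$icrs, config)

  # refine ICR boundaries from maternal-KO hypomethylated CpGs
  hypo_mko <- if ("mKO_vs_WT" %in% names(site_dml))
    site_dml[["mKO_vs_WT"]][status == "hypo", .(chrom, pos)]
  else data.table(chrom = character(), pos = integer())
  icr_refined <- refine_icrs(study$icrs, hypo_mko, config)

  # concordance: zygotic-KO groups traced into the other comparisons
  concordance <- NULL; common_sites <- NULL
  if (all(c("KO_vs_WT", "mzKO_vs_WT", "mKO_vs_WT") %in% names(tile_dml))) {
    others <- c("mzKO_vs_WT", "mKO_vs_WT")
    conc_rows <- list()
    for (grp in c("A", "B")) {
      ext <- extract_group(tile_dml[["KO_vs_WT"]], grp, config)
      units <- common_units(ext, tile_dml[others])
      if (length(units)) {
        res <- lapply(tile_dml[others], function(rec)
          concordance_fraction(units, rec, grp, config))
        conc_rows[[grp]] <- concordance_table(res, "KO_vs_WT")
      }
    }
    concordance <- rbindlist(conc_rows)
    common_sites <- common_hypo_sites(site_dml[["KO_vs_WT"]],
                                      site_dml[["mzKO_vs_WT"]], config)
  }

  summary <- rbindlist(lapply(names(site_dml), function(lbl) data.table(
    comparison = lbl,
    sites_qualified = site_dml[[lbl]][status != "unqualified", .N],
    sites_hypo = site_dml[[lbl]][status == "hypo", .N],
    sites_hyper = site_dml[[lbl]][status == "hyper", .N],
    tiles_qualified = tile_dml[[lbl]][status != "unqualified", .N],
    tiles_hypo = tile_dml[[lbl]][status == "hypo", .N],
    tiles_hyper = tile_dml[[lbl]][status == "hyper", .N]
  )))

  manifest <- list(
    tool = "methdiffr",
    version = as.character(packageVersion("methdiffr")),
    seed = study$seed,
    params = study$params,
    config = unclass(config)[setdiff(names(config), "seed")],
    comparisons = names(cmps)
  )

  files <- character(0)
  if (!is.null(out_dir)) {
    for (lbl in names(site_dml)) {
      f <- file.path(out_dir, sprintf("site_dml_%s.tsv", lbl))
      write_dm_table(site_dml[[lbl]], f); files <- c(files, f)
      f <- file.path(out_dir, sprintf("tile_dml_%s.tsv", lbl))
      write_dm_table(tile_dml[[lbl]], f); files <- c(files, f)
    }
    f <- file.path(out_dir, "icr_summary.tsv")
    fwrite(icr_summary, f, sep = "\t"); files <- c(files, f)
    f <- file.path(out_dir, "icrs_refined.bed")
    write_bed(icr_refined$regions, f); files <- c(files, f)
    f <- file.path(out_dir, "icr_refinement_log.tsv")
    fwrite(icr_refined$log, f, sep = "\t"); files <- c(files, f)
    if (!is.null(concordance) && nrow(concordance)) {
      f <- file.path(out_dir, "concordance.tsv")
      fwrite(concordance, f, sep = "\t"); files <- c(files, f)
    }
    f <- file.path(out_dir, "summary.tsv")
    fwrite(summary, f, sep = "\t"); files <- c(files, f)
    manifest$outputs <- basename(files)
    # written atomically: compose, then rename into place
    tmp <- tempfile(tmpdir = out_dir)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    file.rename(tmp, file.path(out_dir, "run_manifest.json"))
  }

  structure(list(site_dml = site_dml, tile_dml = tile_dml,
                 icr_summary = icr_summary, icr_refined = icr_refined,
                 concordance = concordance, common_sites = common_sites,
                 summary = summary, manifest = manifest),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat("<study_results>\n")
  print(x$summary)
  invisible(x)
}
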
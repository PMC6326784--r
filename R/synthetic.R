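#' Synthetic genome specification
#'
#' Describes the simulated RRBS landscape: chromosome lengths, CpG density,
#' gene and ICR placement, and the set of DNMT3A-target tiles carrying the
#' planted zygotic-KO effect. Defaults emulate the structure of the real
#' post-alignment data: a bimodal CpG methylation landscape (most sites
#' below 20% or above 80%), ICRs at ~50% in WT from monoallelic
#' methylation, and coverage deep enough that most sites clear the 20x
#' qualification filter.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param cpg_spacing mean CpG spacing in bp (geometric-like gaps, min 2).
#' @param n_genes number of gene models to place.
#' @param gene_size length-2 range of gene sizes (bp).
#' @param n_icrs number of ICRs.
#' @param icr_size ICR width (bp).
#' @param target_tile_fraction fraction of CpG-bearing tiles designated as
#'   DNMT3A targets (disjoint from ICR-overlapping tiles).
#' @param tile_width tile width used to define target tiles (bp).
#' @param mix_weights mixture weights of the background site-level classes
#'   (low, mid, high).
#' @param beta_low,beta_high Beta shape pairs of the low and high mixture
#'   components.
#' @param mid_range uniform range of the mid component.
#' @param target_mid_fraction fraction of target-tile sites drawn from the
#'   partially methylated component (the rest are highly methylated);
#'   target regions are methylated in WT, as the planted loss presupposes.
#' @param target_mid_range uniform range of the target-tile mid component.
#' @param mid_concentration Beta concentration of site levels around their
#'   tile's partial-methylation mean (larger = tighter regional coherence).
#' @param cov_factor_shape shape of the Gamma(shape, shape) per-site coverage
#'   propensity shared by all samples (RRBS depth is locus-driven: the same
#'   MspI fragments are deep in every library); larger values mean more even
#'   coverage.
#' @return list of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(chrom_lengths = c(chr1 = 1500000L,
                                                    chr2 = 1500000L),
                                  cpg_spacing = 80,
                                  n_genes = 60L,
                                  gene_size = c(5000L, 50000L),
                                  n_icrs = 8L,
                                  icr_size = 2000L,
                                  target_tile_fraction = 0.05,
                                  tile_width = 500L,
                                  mix_weights = c(low = 0.35, mid = 0.15,
                                                  high = 0.50),
                                  beta_low = c(1, 19),
                                  beta_high = c(19, 1),
                                  mid_range = c(0.2, 0.8),
                                  target_mid_fraction = 0.3,
                                  target_mid_range = c(0.5, 0.8),
                                  mid_concentration = 30,
                                  cov_factor_shape = 3) {
  stopifnot(length(chrom_lengths) >= 1L, !is.null(names(chrom_lengths)),
            cpg_spacing > 2, n_icrs >= 0, icr_size > 0,
            target_tile_fraction >= 0, target_tile_fraction < 1,
            abs(sum(mix_weights) - 1) < 1e-9)
  structure(as.list(environment()), class = "synthetic_genome_spec")
}

# random CpG positions along one chromosome: gaps of 2 + geometric-like
# exponential spacing around the requested mean
sample_cpg_positions <- function(len, spacing) {
  n_guess <- ceiling(len / spacing * 1.5) + 100L
  gaps <- 2L + pmax(0L, as.integer(round(rexp(n_guess, 1 / (spacing - 2)))))
  pos <- cumsum(gaps)
  pos[pos <= len - 2L]
}

# non-overlapping random intervals of fixed width
sample_regions <- function(n, width, chrom_lengths, prefix) {
  out <- data.table(name = character(), chrom = character(),
                    start = integer(), end = integer())
  attempts <- 0L
  while (nrow(out) < n && attempts < 1000L * n) {
    attempts <- attempts + 1L
    ch <- sample(names(chrom_lengths), 1L)
    st <- sample.int(chrom_lengths[[ch]] - width - 1L, 1L)
    if (out[chrom == ch & start < st + width & end > st, .N] > 0L) next
    out <- rbind(out, data.table(name = sprintf("%s_%d", prefix,
                                                nrow(out) + 1L),
                                 chrom = ch, start = st,
                                 end = st + width))
  }
  if (nrow(out) < n) stopf("could not place %d non-overlapping regions", n)
  out[order(chrom, start)]
}

# random gene models with 1-6 exons
sample_genes <- function(n, size_range, chrom_lengths) {
  genes <- lapply(seq_len(n), function(i) {
    chrom <- sample(names(chrom_lengths), 1L)
    size <- sample(size_range[1]:size_range[2], 1L)
    tx_start <- sample.int(max(chrom_lengths[[chrom]] - size - 10000L, 1L), 1L) + 5000L
    tx_end <- tx_start + size
    n_exon <- sample.int(6L, 1L)
    cuts <- sort(sample(seq(tx_start + 1L, tx_end - 1L), 2L * n_exon - 2L))
    bounds <- c(tx_start, cuts, tx_end)
    es <- bounds[seq(1L, length(bounds), by = 2L)]
    ee <- bounds[seq(2L, length(bounds), by = 2L)]
    gene_model(name = sprintf("gene_%d", i), chrom = chrom,
               strand = sample(c("+", "-"), 1L),
               tx_start = tx_start, tx_end = tx_end,
               exon_starts = es, exon_ends = ee)
  })
  out <- rbindlist(genes)
  setattr(out, "class", c("gene_models", class(out)))
  out[]
}

#' Simulate a ground-truth WT methylome
#'
#' Draws per-CpG true methylation levels from a three-part mixture
#' (bimodal background: low Beta, partially methylated, high Beta). The
#' mixture component is assigned per 500-bp tile and shared by the tile's
#' sites — methylation is regionally coherent in real data — with
#' partially methylated tiles scattering their sites around a tile mean
#' drawn uniformly from `mid_range`. ICR sites carry the monoallelic pair
#' (1, 0) — expected observed level 0.5. DNMT3A-target tiles draw from the
#' methylated components only (they are methylated in WT; the planted loss
#' presupposes it). Each site also receives a coverage propensity shared by
#' all samples. Deterministic given the seed.
#'
#' @param spec a [synthetic_genome_spec].
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return list of class `truth_table`: `truth` (`data.table` with `chrom`,
#'   `pos`, `class_` in \{none, icr, target\}, `icr_name`, `level`,
#'   `allele1`, `allele2`), `icrs`, `genes`, `target_tiles` (tile ids),
#'   `spec`, `seed`.
#' @export
simulate_methylome <- function(spec = synthetic_genome_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sites <- rbindlist(lapply(names(spec$chrom_lengths), function(ch)
    data.table(chrom = ch,
               pos = sample_cpg_positions(spec$chrom_lengths[[ch]],
                                          spec$cpg_spacing))))
  icrs <- sample_regions(spec$n_icrs, spec$icr_size, spec$chrom_lengths,
                         "ICR")
  genes <- sample_genes(spec$n_genes, spec$gene_size, spec$chrom_lengths)

  sites[, icr_name := overlap_icr(sites, icrs)]
  sites[, tile_id := sprintf("%s:%d-%d", chrom,
                             tile_start_of(pos, spec$tile_width),
                             tile_start_of(pos, spec$tile_width) +
                               spec$tile_width)]
  tile_counts <- sites[, .(n = .N, any_icr = any(!is.na(icr_name))),
                       by = tile_id]
  eligible <- tile_counts[n >= 3L & !any_icr, tile_id]
  n_target <- round(spec$target_tile_fraction * nrow(tile_counts))
  target_tiles <- sort(sample(eligible, min(n_target, length(eligible))))

  sites[, class_ := "none"]
  sites[!is.na(icr_name), class_ := "icr"]
  sites[class_ == "none" & tile_id %in% target_tiles, class_ := "target"]

  # methylation is regionally coherent: the mixture component is drawn per
  # tile and shared by its member sites, so the marginal site-level mixture
  # is preserved while 500-bp windows stay internally homogeneous
  tiles <- unique(sites$tile_id)
  comp_by_tile <- setNames(sample(c("low", "mid", "high"), length(tiles),
                                  replace = TRUE, prob = spec$mix_weights),
                           tiles)
  mid_mean_by_tile <- setNames(runif(length(tiles), spec$mid_range[1],
                                     spec$mid_range[2]), tiles)
  n <- nrow(sites)
  comp <- comp_by_tile[sites$tile_id]
  level <- numeric(n)
  level[comp == "low"] <- rbeta(sum(comp == "low"),
                                spec$beta_low[1], spec$beta_low[2])
  level[comp == "high"] <- rbeta(sum(comp == "high"),
                                 spec$beta_high[1], spec$beta_high[2])
  is_mid <- comp == "mid"
  if (any(is_mid)) {
    # sites scatter around the tile's partial-methylation mean
    m <- mid_mean_by_tile[sites$tile_id[is_mid]]
    k <- spec$mid_concentration
    level[is_mid] <- rbeta(sum(is_mid), m * k, (1 - m) * k)
  }
  is_tgt <- sites$class_ == "target"
  if (any(is_tgt)) {
    tgt_tiles <- unique(sites$tile_id[is_tgt])
    tgt_mid_tile <- setNames(runif(length(tgt_tiles)) <
                               spec$target_mid_fraction, tgt_tiles)
    tgt_mean <- setNames(runif(length(tgt_tiles), spec$target_mid_range[1],
                               spec$target_mid_range[2]), tgt_tiles)
    mid_t <- is_tgt & tgt_mid_tile[sites$tile_id]
    high_t <- is_tgt & !tgt_mid_tile[sites$tile_id]
    if (any(mid_t)) {
      m <- tgt_mean[sites$tile_id[mid_t]]
      k <- spec$mid_concentration
      level[mid_t] <- rbeta(sum(mid_t), m * k, (1 - m) * k)
    }
    if (any(high_t))
      level[high_t] <- rbeta(sum(high_t), spec$beta_high[1],
                             spec$beta_high[2])
  }
  sites[, level := level]
  sites[, `:=`(allele1 = NA_real_, allele2 = NA_real_)]
  sites[class_ == "icr", `:=`(allele1 = 1, allele2 = 0, level = 0.5)]
  # per-site coverage propensity shared by all samples: RRBS depth is a
  # property of the locus (fragment size, CpG density), so deep sites are
  # deep in every sample
  sites[, cov_factor := rgamma(.N, shape = spec$cov_factor_shape,
                               rate = spec$cov_factor_shape)]
  sites[, tile_id := NULL]
  setkey(sites, chrom, pos)
  structure(list(truth = sites[], icrs = icrs, genes = genes,
                 target_tiles = target_tiles, spec = spec, seed = seed),
            class = "truth_table")
}

#' Apply a genotype effect to a ground-truth methylome
#'
#' WT is the identity. mKO (maternal KO) zeroes both ICR alleles and leaves
#' all other sites unchanged (imprints are never re-established). KO
#' (zygotic KO) subtracts `effect_delta` from target-tile site levels,
#' floored at 0, with ICR sites untouched (they are fully resistant to
#' zygotic loss). mzKO applies both.
#'
#' @param truth a `truth_table` from [simulate_methylome].
#' @param genotype one of "WT", "mKO", "KO", "mzKO".
#' @param effect_delta methylation loss planted at target-tile sites (on the
#'   `[0, 1]` level scale).
#' @return a `truth_table` with genotype-adjusted levels; the `genotype`
#'   field records the label.
#' @export
apply_genotype <- function(truth, genotype, effect_delta = 0.30) {
  if (!genotype %in% c("WT", "mKO", "KO", "mzKO"))
    stopf("unknown genotype '%s'", genotype)
  out <- truth
  out$truth <- copy(truth$truth)
  if (genotype %in% c("mKO", "mzKO")) {
    out$truth[class_ == "icr", `:=`(allele1 = 0, allele2 = 0, level = 0)]
  }
  if (genotype %in% c("KO", "mzKO")) {
    out$truth[class_ == "target", level := pmax(level - effect_delta, 0)]
  }
  out$genotype <- genotype
  out
}

# conversion-adjusted observed methylation probability of a true level:
# unconverted unmethylated cytosines read as methylated
adjust_level <- function(level, conv_fail, over_conv = 0) {
  level * (1 - over_conv) + (1 - level) * conv_fail
}

#' Emit Bismark-format counts for one genotype
#'
#' For each replicate, per-site coverage is drawn from a shifted negative
#' binomial (minimum 1 read) and methylated counts from a binomial at the
#' conversion-adjusted true level. ICR sites are sampled allele-first: reads
#' are split between the two parental alleles Binomial(cov, 0.5) and each
#' allele contributes reads at its own level, so observed ICR methylation is
#' genuinely binomial around 50% rather than a flat per-read coin. A matched
#' non-CpG cytosine pool measures the conversion failure rate.
#'
#' @param truth a (genotype-adjusted) `truth_table`.
#' @param n_replicates number of replicates to emit.
#' @param mean_cov negative binomial mean coverage.
#' @param conv_fail bisulfite conversion failure probability (unconverted C
#'   read as methylated); must be < 0.05.
#' @param seed integer seed (`NULL` to continue the current RNG stream).
#' @param genotype genotype label for the emitted samples.
#' @param sample_prefix prefix of emitted sample ids.
#' @param nb_dispersion negative binomial size parameter.
#' @param n_noncpg number of non-CpG cytosines in the conversion QC pool per
#'   replicate.
#' @param out_dir if non-`NULL`, write one Bismark coverage file per
#'   replicate plus a conversion QC TSV into this directory.
#' @return list with `call_sets` (list of [meth_call_set]), `conversion`
#'   (`data.table`: sample_id, n_converted, n_unconverted) and `files`
#'   (paths written, or `NULL`).
#' @export
emit_counts <- function(truth, n_replicates = 3L, mean_cov = 30,
                        conv_fail = 0.005, seed = NULL,
                        genotype = truth$genotype %||% "WT",
                        sample_prefix = genotype, nb_dispersion = 5,
                        n_noncpg = 20000L, out_dir = NULL) {
  stopifnot(mean_cov >= 1, conv_fail >= 0, conv_fail < 0.05)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  tt <- truth$truth
  n <- nrow(tt)
  is_icr <- tt$class_ == "icr"
  files <- character(0)
  call_sets <- vector("list", n_replicates)
  conv <- vector("list", n_replicates)
  cov_factor <- if ("cov_factor" %in% names(tt)) tt$cov_factor else rep(1, n)
  for (r in seq_len(n_replicates)) {
    sid <- sprintf("%s_rep%d", sample_prefix, r)
    cov <- 1L + rnbinom(n, size = nb_dispersion,
                        mu = (mean_cov - 1) * cov_factor)
    meth <- integer(n)
    if (any(!is_icr)) {
      lv <- adjust_level(tt$level[!is_icr], conv_fail)
      meth[!is_icr] <- rbinom(sum(!is_icr), cov[!is_icr], lv)
    }
    if (any(is_icr)) {
      cov_a1 <- rbinom(sum(is_icr), cov[is_icr], 0.5)
      l1 <- adjust_level(tt$allele1[is_icr], conv_fail)
      l2 <- adjust_level(tt$allele2[is_icr], conv_fail)
      meth[is_icr] <- rbinom(sum(is_icr), cov_a1, l1) +
        rbinom(sum(is_icr), cov[is_icr] - cov_a1, l2)
    }
    calls <- data.table(chrom = tt$chrom, pos = tt$pos, n_meth = meth,
                        n_unmeth = cov - meth)
    call_sets[[r]] <- meth_call_set(sid, genotype, calls)
    n_unconv <- rbinom(1L, n_noncpg, conv_fail)
    conv[[r]] <- data.table(sample_id = sid,
                            n_converted = n_noncpg - n_unconv,
                            n_unconverted = n_unconv)
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, sprintf("%s.cov", sid))
      out <- calls[, .(chrom, pos, pos2 = pos,
                       pct = sprintf("%.6f", 100 * n_meth /
                                       (n_meth + n_unmeth)),
                       n_meth, n_unmeth)]
      fwrite(out, path, sep = "\t", col.names = FALSE)
      files <- c(files, path)
    }
  }
  conversion <- rbindlist(conv)
  if (!is.null(out_dir)) {
    path <- file.path(out_dir, sprintf("%s_conversion.tsv", sample_prefix))
    fwrite(conversion, path, sep = "\t")
    files <- c(files, path)
  }
  list(call_sets = call_sets, conversion = conversion,
       files = if (length(files)) files else NULL)
}

#' Write gene models as a genePred table
#'
#' @param genes `gene_models` table.
#' @param path output path.
#' @export
write_genepred <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i]
    es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
    paste(g$name, g$chrom, g$strand, g$tx_start, g$tx_end, g$tx_start,
          g$tx_end, length(es),
          paste0(paste(es, collapse = ","), ","),
          paste0(paste(ee, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a full synthetic study
#'
#' One shared genome specification, one ground-truth methylome, and
#' replicated Bismark-format count sets for the four genotypes (WT, mKO, KO,
#' mzKO), with a shared CpG map so qualification differences between
#' genotypes come only from coverage sampling. The whole dataset is a pure
#' function of (spec, parameters, seed).
#'
#' @param spec a [synthetic_genome_spec].
#' @param seed integer seed.
#' @param n_replicates replicates per genotype: a scalar, or a named vector
#'   like `c(WT = 3, KO = 2, ...)` (the study discarded one zygotic-KO
#'   replicate; set `KO = 2` to reproduce that).
#' @param mean_cov mean coverage per site.
#' @param conv_fail conversion failure probability.
#' @param effect_delta planted target-tile loss on the level scale.
#' @param genotypes genotypes to emit.
#' @param out_dir if non-`NULL`, write coverage files, truth tables, an ICR
#'   BED, a genePred gene table, the conversion QC TSV and a JSON run
#'   manifest here.
#' @return list of class `synthetic_study`: `call_sets` (named by genotype:
#'   lists of [meth_call_set]), `truths` (per-genotype `truth_table`),
#'   `genome` (the WT truth), `icrs`, `genes`, `target_tiles`, `conversion`,
#'   `spec`, `seed`, `params`, `files`.
#' @export
make_study <- function(spec = synthetic_genome_spec(), seed = 1L,
                       n_replicates = 3L, mean_cov = 30, conv_fail = 0.005,
                       effect_delta = 0.30,
                       genotypes = c("WT", "mKO", "KO", "mzKO"),
                       out_dir = NULL) {
  set.seed(seed)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  reps <- if (length(n_replicates) == 1L && is.null(names(n_replicates)))
    setNames(rep(as.integer(n_replicates), length(genotypes)), genotypes)
  else {
    stopifnot(all(genotypes %in% names(n_replicates)))
    vapply(genotypes, function(g) as.integer(n_replicates[[g]]),
           integer(1))
  }
  genome <- simulate_methylome(spec, seed = NULL)
  call_sets <- list(); truths <- list(); conv <- list()
  files <- character(0)
  for (g in genotypes) {
    truths[[g]] <- apply_genotype(genome, g, effect_delta)
    em <- emit_counts(truths[[g]], n_replicates = reps[[g]],
                      mean_cov = mean_cov, conv_fail = conv_fail,
                      seed = NULL, genotype = g, out_dir = out_dir)
    call_sets[[g]] <- em$call_sets
    conv[[g]] <- em$conversion
    files <- c(files, em$files %||% character(0))
  }
  conversion <- rbindlist(conv)
  params <- list(seed = seed, n_replicates = as.list(reps),
                 mean_cov = mean_cov, conv_fail = conv_fail,
                 effect_delta = effect_delta,
                 chrom_lengths = as.list(spec$chrom_lengths),
                 cpg_spacing = spec$cpg_spacing, n_icrs = spec$n_icrs,
                 icr_size = spec$icr_size,
                 target_tile_fraction = spec$target_tile_fraction)
  if (!is.null(out_dir)) {
    tbed <- file.path(out_dir, "icrs.bed")
    write_bed(genome$icrs, tbed)
    tgp <- file.path(out_dir, "genes.genePred")
    write_genepred(genome$genes, tgp)
    ttsv <- file.path(out_dir, "truth_wt.tsv")
    fwrite(genome$truth, ttsv, sep = "\t")
    tman <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(list(tool = "methdiffr",
                              version = as.character(packageVersion("methdiffr")),
                              params = params),
                         tman, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, tbed, tgp, ttsv, tman)
  }
  structure(list(call_sets = call_sets, truths = truths, genome = genome,
                 icrs = genome$icrs, genes = genome$genes,
                 target_tiles = genome$target_tiles,
                 conversion = conversion, spec = spec, seed = seed,
                 params = params,
                 files = if (length(files)) files else NULL),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> seed %s: %d CpGs, %d ICRs, %d target tiles; genotypes: %s\n",
              format(x$seed), nrow(x$genome$truth), nrow(x$icrs),
              length(x$target_tiles),
              paste(sprintf("%s x%d", names(x$call_sets),
                            lengths(x$call_sets)), collapse = ", ")))
  invisible(x)
}
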
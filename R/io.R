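#' Methylation call set
#'
#' Container for one sample's CpG methylation counts: a `data.table` with
#' columns `chrom`, `pos` (1-based position of the cytosine), `n_meth` and
#' `n_unmeth`, keyed and unique on (`chrom`, `pos`), plus the sample id and
#' genotype label.
#'
#' @param sample_id non-empty sample identifier.
#' @param genotype genotype label (e.g. "WT", "KO", "mKO", "mzKO").
#' @param calls data.frame/data.table with columns `chrom`, `pos`, `n_meth`,
#'   `n_unmeth`.
#' @return object of class `meth_call_set`.
#' @export
meth_call_set <- function(sample_id, genotype, calls) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stopf("sample_id must be a non-empty string")
  calls <- as.data.table(calls)
  need <- c("chrom", "pos", "n_meth", "n_unmeth")
  if (!all(need %in% names(calls)))
    stopf("calls must have columns %s", paste(need, collapse = ", "))
  calls <- calls[, .(chrom = as.character(chrom), pos = as.integer(pos),
                     n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth))]
  if (nrow(calls)) {
    if (any(calls$pos < 1L)) stopf("positions must be >= 1")
    if (any(calls$n_meth < 0L) || any(calls$n_unmeth < 0L))
      stopf("counts must be non-negative")
    if (anyDuplicated(calls, by = c("chrom", "pos")))
      stopf("duplicate (chrom, pos) in call set '%s'", sample_id)
  }
  setkey(calls, chrom, pos)
  structure(list(sample_id = sample_id, genotype = as.character(genotype),
                 calls = calls),
            class = "meth_call_set")
}

#' @export
print.meth_call_set <- function(x, ...) {
  cat(sprintf("<meth_call_set> %s (%s): %d CpG sites\n",
              x$sample_id, x$genotype, nrow(x$calls)))
  invisible(x)
}

#' Recomputed methylation percentages of a call set
#'
#' @param x a `meth_call_set`.
#' @return numeric vector, `100 * n_meth / (n_meth + n_unmeth)` per site.
#' @export
call_percents <- function(x) {
  with(x$calls, 100 * n_meth / (n_meth + n_unmeth))
}

# Merge the two strand calls of a CpG dyad (pos, pos + 1) by summing counts.
# Pairs are anchored at the odd member of each run: a call at pos is merged
# into pos - 1 when a call exists there and none exists at pos - 2 claiming it.
destrand_calls <- function(calls) {
  calls <- copy(calls)[order(chrom, pos)]
  calls[, anchor := pos]
  prev_pos <- shift(calls$pos)
  prev_chr <- shift(calls$chrom)
  is_partner <- !is.na(prev_pos) & calls$chrom == prev_chr & calls$pos == prev_pos + 1L
  # a row already merged into its predecessor cannot anchor the next row
  for (i in which(is_partner)) {
    if (i > 1L && calls$anchor[i - 1L] != calls$pos[i - 1L]) next
    calls$anchor[i] <- calls$pos[i] - 1L
  }
  out <- calls[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
               by = .(chrom, pos = anchor)]
  setkey(out, chrom, pos)
  out[]
}

#' Read a Bismark coverage file
#'
#' Parses the 6-column Bismark coverage format (chrom, start, end,
#' methylation percentage, count methylated, count unmethylated; positions
#' 1-based). The percentage column is advisory only: percentages are
#' recomputed from the counts, and a warning is raised when a stated
#' percentage disagrees with its counts by more than 0.5 points. Lines with
#' zero coverage are dropped with a warning. Gzip-compressed files are read
#' transparently.
#'
#' @param path file path.
#' @param sample_id sample identifier to attach.
#' @param genotype genotype label to attach.
#' @param destrand merge CpG dyad strand calls at (pos, pos + 1) by summing
#'   counts (default off: calls are used as extracted).
#' @return a [meth_call_set].
#' @export
read_bismark_coverage <- function(path, sample_id, genotype = NA_character_,
                                  destrand = FALSE) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- read_raw_tsv(path)
  if (nrow(raw) == 0L)
    return(meth_call_set(sample_id, genotype,
                         data.table(chrom = character(), pos = integer(),
                                    n_meth = integer(), n_unmeth = integer())))
  if (ncol(raw) != 6L)
    stopf("%s: expected 6 tab-separated columns, found %d", path, ncol(raw))
  suppressWarnings({
    pos <- as.numeric(raw[[2]])
    pct <- as.numeric(raw[[4]])
    nm <- as.numeric(raw[[5]])
    nu <- as.numeric(raw[[6]])
  })
  bad <- which(is.na(pos) | is.na(nm) | is.na(nu) |
                 nm != floor(nm) | nu != floor(nu) | nm < 0 | nu < 0)
  if (length(bad))
    stopf("%s: malformed counts at line %d", path, bad[1])
  dt <- data.table(chrom = raw[[1]], pos = as.integer(pos),
                   n_meth = as.integer(nm), n_unmeth = as.integer(nu),
                   stated_pct = pct)
  dup <- which(duplicated(dt, by = c("chrom", "pos")))
  if (length(dup))
    stopf("%s: duplicate site %s:%d at line %d",
          path, dt$chrom[dup[1]], dt$pos[dup[1]], dup[1])
  zero <- dt$n_meth + dt$n_unmeth == 0L
  if (any(zero)) {
    warnf("%s: dropping %d line(s) with zero coverage", path, sum(zero))
    dt <- dt[!zero]
  }
  if (nrow(dt)) {
    recomputed <- 100 * dt$n_meth / (dt$n_meth + dt$n_unmeth)
    off <- !is.na(dt$stated_pct) & abs(dt$stated_pct - recomputed) > 0.5
    if (any(off))
      warnf("%s: %d stated percentage(s) disagree with counts; counts kept",
            path, sum(off))
  }
  dt[, stated_pct := NULL]
  if (isTRUE(destrand)) dt <- destrand_calls(dt)
  meth_call_set(sample_id, genotype, dt)
}

#' Read a genePred/refFlat gene table
#'
#' Accepts the 10-column genePred layout (name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds) or the 11-column
#' refFlat layout with a leading geneName column. Coordinates are 0-based
#' half-open as in the source format; trailing commas in exon lists are
#' tolerated. Strand is recorded as given; no coordinate flipping happens at
#' load time.
#'
#' @param path file path (gzip transparent).
#' @return `data.table` of class `gene_models` with columns `name`, `chrom`,
#'   `strand`, `tx_start`, `tx_end` and list-columns `exon_starts`,
#'   `exon_ends`.
#' @export
read_genepred <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- read_raw_tsv(path)
  if (nrow(raw) == 0L) return(empty_gene_models())
  off <- if (ncol(raw) >= 11L) 1L else 0L  # refFlat has geneName first
  if (ncol(raw) < 10L)
    stopf("%s: expected >= 10 genePred columns, found %d", path, ncol(raw))
  parse_list <- function(s) as.integer(strsplit(sub(",+$", "", s), ",")[[1]])
  genes <- lapply(seq_len(nrow(raw)), function(i) {
    r <- unlist(raw[i])
    es <- parse_list(r[[off + 9L]])
    ee <- parse_list(r[[off + 10L]])
    n_exon <- as.integer(r[[off + 8L]])
    if (length(es) != n_exon || length(ee) != n_exon)
      stopf("%s line %d: exon list length (%d/%d) does not match exonCount %d",
            path, i, length(es), length(ee), n_exon)
    gene_model(name = r[[off + 1L]], chrom = r[[off + 2L]],
               strand = r[[off + 3L]],
               tx_start = as.integer(r[[off + 4L]]),
               tx_end = as.integer(r[[off + 5L]]),
               exon_starts = es, exon_ends = ee)
  })
  out <- rbindlist(genes)
  setattr(out, "class", c("gene_models", class(out)))
  out[]
}

empty_gene_models <- function() {
  out <- data.table(name = character(), chrom = character(),
                    strand = character(), tx_start = integer(),
                    tx_end = integer(), exon_starts = list(),
                    exon_ends = list())
  setattr(out, "class", c("gene_models", class(out)))
  out[]
}

#' Construct a single gene model
#'
#' @param name gene name.
#' @param chrom chromosome.
#' @param strand "+" or "-".
#' @param tx_start,tx_end transcript span, 0-based half-open.
#' @param exon_starts,exon_ends parallel integer vectors, 0-based half-open,
#'   sorted and non-overlapping, within the transcript span.
#' @return one-row `gene_models` table.
#' @export
gene_model <- function(name, chrom, strand, tx_start, tx_end,
                       exon_starts = tx_start, exon_ends = tx_end) {
  if (!strand %in% c("+", "-")) stopf("gene %s: strand must be + or -", name)
  if (tx_start >= tx_end) stopf("gene %s: tx_start >= tx_end", name)
  if (length(exon_starts) != length(exon_ends))
    stopf("gene %s: exon list length mismatch", name)
  if (length(exon_starts)) {
    if (any(exon_starts >= exon_ends))
      stopf("gene %s: empty or inverted exon", name)
    if (is.unsorted(exon_starts) ||
        any(exon_starts[-1] < exon_ends[-length(exon_ends)]))
      stopf("gene %s: exons must be sorted and non-overlapping", name)
    if (exon_starts[1] < tx_start || exon_ends[length(exon_ends)] > tx_end)
      stopf("gene %s: exons outside transcript span", name)
  }
  out <- data.table(name = name, chrom = chrom, strand = strand,
                    tx_start = as.integer(tx_start),
                    tx_end = as.integer(tx_end),
                    exon_starts = list(as.integer(exon_starts)),
                    exon_ends = list(as.integer(exon_ends)))
  setattr(out, "class", c("gene_models", class(out)))
  out[]
}

#' Read a BED3/BED4 interval file
#'
#' Intervals are 0-based half-open as in BED. Unnamed regions receive
#' synthetic names `region_1`, `region_2`, ... in file order.
#'
#' @param path file path (gzip transparent).
#' @return `data.table` with columns `name`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- read_raw_tsv(path)
  if (nrow(raw) == 0L)
    return(data.table(name = character(), chrom = character(),
                      start = integer(), end = integer()))
  if (ncol(raw) < 3L) stopf("%s: BED needs at least 3 columns", path)
  out <- data.table(chrom = raw[[1]],
                    start = as.integer(raw[[2]]),
                    end = as.integer(raw[[3]]))
  out[, name := if (ncol(raw) >= 4L) raw[[4]] else NA_character_]
  out[is.na(name) | !nzchar(name), name := sprintf("region_%d", .I)]
  bad <- which(out$start >= out$end)
  if (length(bad))
    stopf("%s line %d: start >= end (%d >= %d)",
          path, bad[1], out$start[bad[1]], out$end[bad[1]])
  setcolorder(out, c("name", "chrom", "start", "end"))
  out[]
}

#' Write regions as BED4
#'
#' @param regions `data.table` with `name`, `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  dt <- as.data.table(regions)[order(chrom, start, end)]
  fwrite(dt[, .(chrom, start, end, name)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

# fread wrapper tolerating empty files (fread warns on size-0 input)
read_raw_tsv <- function(path) {
  raw <- suppressWarnings(fread(path, header = FALSE, sep = "\t",
                                colClasses = "character", fill = TRUE))
  if (is.null(raw) || !nrow(raw)) data.table() else raw
}

dm_table_columns <- c("unit", "chrom", "start", "end", "meth_test",
                      "meth_ctrl", "diff", "p", "q", "status", "location",
                      "icr")

#' Write a differential-methylation table
#'
#' Writes DM records as a deterministic TSV sorted by (chrom, start, end):
#' unit id, 0-based half-open coordinates, per-group methylation percentages,
#' difference, p, q, status and (when present) location and ICR columns.
#' Numeric columns are printed with 6 decimals so that writing the same
#' records twice yields byte-identical files and re-reading reproduces the
#' records at that precision.
#'
#' @param records DM record `data.table` (see [run_site_dml], [run_tile_dml]).
#' @param path output path.
#' @export
write_dm_table <- function(records, path) {
  dt <- as.data.table(records)
  if (!"unit" %in% names(dt)) stopf("records need a 'unit' column")
  if (!"start" %in% names(dt) && "pos" %in% names(dt))
    dt[, `:=`(start = pos - 1L, end = pos)]
  for (col in dm_table_columns)
    if (!col %in% names(dt)) dt[, (col) := NA]
  dt <- dt[, dm_table_columns, with = FALSE][order(chrom, start, end)]
  num <- c("meth_test", "meth_ctrl", "diff", "p", "q")
  for (col in num) {
    v <- as.numeric(dt[[col]])
    dt[, (col) := ifelse(is.na(v), "NA", sprintf("%.6f", v))]
  }
  fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read back a differential-methylation table
#'
#' @param path a TSV written by [write_dm_table].
#' @return DM record `data.table`.
#' @export
read_dm_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, na.strings = "NA",
              colClasses = list(character = c("unit", "chrom", "status")))
  num <- c("meth_test", "meth_ctrl", "diff", "p", "q")
  for (col in num) dt[, (col) := as.numeric(get(col))]
  dt[]
}
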
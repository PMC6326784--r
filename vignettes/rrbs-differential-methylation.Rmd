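---
title: "Differential methylation analysis of RRBS count data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation analysis of RRBS count data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdiffr)
library(data.table)
```

# The problem

Reduced representation bisulfite sequencing (RRBS) measures CpG methylation
as per-site read counts: at each cytosine, some reads are methylated
(protected from bisulfite conversion) and some are not. `methdiffr`
implements the comparative analysis of such count sets across mouse
embryonic stem cell (mESC) genotypes that differ in DNMT3L status — wild
type (WT), maternal-only knockout (mKO), zygotic knockout (KO) and combined
(mzKO) — with the goal of locating where methylation is lost, classifying
its severity, and tracing whether the affected regions behave like DNMT3A
targets. Imprinting control regions (ICRs) play a special role: they are
methylated on exactly one parental allele, so they sit near 50% in WT cells,
collapse when the maternal imprint was never established (mKO, mzKO), and
are fully resistant to zygotic loss (KO).

Because the original sequencing data cannot ship with a package, a
first-class synthetic generator (`make_study()`) produces Bismark-format
coverage files with the statistical structure the analysis assumes, plus
ground-truth tables, so every stage is testable end to end.

# Statistical model

## Qualification

Units enter testing only when measured well everywhere:

* a **CpG site** qualifies when its read coverage is at least
  `min_site_cov` (default 20 reads) in *every* sample of both groups;
* a **500-bp tile** qualifies when at least `tile_min_cpgs` (3) of its
  member CpGs have coverage at least `tile_min_cov` (10) in every sample.
  A site counts toward the three only if it clears the bar in *all*
  samples — the only reading that makes tiles comparable across samples.

Tiles are fixed, ungapped windows anchored at 0-based multiples of the tile
width from the chromosome origin; a 1-based site at `pos` belongs to tile
`floor((pos - 1) / width)`. The anchoring phase is a convention (deterministic
and the common tiling practice); analyses that tiled from a different origin
would paint slightly different tile boundaries.

## Testing

Counts are pooled per group (coverage-weighted), never averaged across
per-sample percentages, so the summary matches the count-based test.

* With replicates in either group, each unit is tested by **binomial
  logistic regression** of the methylated proportion on a group indicator,
  with a likelihood-ratio statistic against the intercept-only null referred
  to chi-square with 1 df. With one binary covariate and grouped binomial
  counts the maximum-likelihood fit is available in closed form — the fitted
  proportion of each group is its pooled proportion — so the statistic is
  computed directly and vectorised; the test suite verifies the statistic
  equals the deviance difference of the corresponding `glm()` IRLS fits to
  1e-8. No overdispersion correction is applied.
* For 1-vs-1 comparisons, a **two-sided Fisher exact test** on the pooled
  2x2 table, computed by hypergeometric tail summation (all tables with the
  observed margins whose probability does not exceed the observed table's,
  with the customary `1 + 1e-7` tie tolerance). Degenerate tables (a zero
  margin) return p = 1 with a warning.

P-values are adjusted by **Benjamini–Hochberg** step-up over the qualified
units of each comparison (`stats::p.adjust`, cross-checked in tests against
a quadratic-time min-over-suffix computation). This is a deliberate,
documented deviation from the q-value procedure some methylation toolkits
default to (SLIM): BH is deterministic, assumption-light and exactly
testable, and the downstream threshold (q <= 0.01) is applied identically.

## Calling and classification

A qualified unit is called **hypomethylated** when its difference
(test minus control) is <= -25 percentage points with q <= 0.01, and
**hypermethylated** symmetrically; both boundaries are inclusive, following
the wording of the published criteria. "True unchanged" units (Group B)
satisfy |difference| < 5 and q > 0.1, both strict, which deliberately
excludes intermediate losses of 5-25%. Methylation states partition
[0, 100]: unmethylated below 20%, partial in [20, 80), high at and above 80%
(the boundary at 80 resolves in favour of the explicit "high" class).

## Annotation

Each site (width-1 query) or tile (any-base overlap) collects every gene
feature category it overlaps across all genes — promoter
[TSS - 1000, TSS + 500), upstream [TSS - 5000, TSS - 1000), TES window
[TES - 500, TES + 1000), downstream [TES + 1000, TES + 5000), all
strand-oriented and half-open, plus annotated exons and the introns between
them — and keeps the highest-priority one:
promoter > upstream > TES > downstream > exon > intron > intergenic.
Categories are pooled across genes *before* resolution, so gene order can
never change the answer. Feature intervals may overlap geometrically; the
priority order, not subtraction, decides. Tiles use any-base overlap (a
midpoint rule would be an alternative; any-overlap was chosen and is flagged
here as a reproducibility caveat).

## ICR summaries and boundary refinement

Per-ICR methylation is the pooled percentage over qualified CpGs inside the
region, per genotype; an ICR without qualified sites is reported missing
(`NA`), never as 0. Boundary refinement generalises two data-driven edits
that are naturally expressed as rules: (a) two same-locus fragments (names
equal after stripping a trailing numeric suffix) separated by at most
`icr_merge_max_gap` (500 bp) merge when hypomethylated CpGs fall in the gap;
(b) a boundary extends outward to the farthest hypomethylated CpG within
`icr_extend_max` (600 bp). The defaults cover gap/extension distances of
346 bp and 549 bp — the two published cases — with headroom; the operation
is idempotent and logs each change with distances.

## Concordance

Group A (hypomethylated) and Group B (unchanged) tiles extracted from one
comparison are first restricted to tiles qualified in every other comparison
("common" tiles), then counted as concordant when the other comparison calls
them hypomethylated (A) or meets the full unchanged criteria (B). Whether a
published "unchanged in the other genotype" bar used the full criteria or
mere non-significance is ambiguous; the full criteria were chosen, and the
count of merely non-significant tiles is emitted alongside. Reported
fractions round half-up to integers (so 87.7% reports as ~88%); exact
fractions and per-unit difference distributions are retained.

## Targeted quantification

* **Clone matrices**: the region percentage pools all clones and CpG
  positions — methylated calls over non-missing calls — rather than
  averaging per-clone percentages, matching percentage-from-multiple-clones
  quantification.
* **Conversion QC**: unmethylated cytosines outside CpG context read as T
  after conversion; the rate of converted / total non-CpG cytosines must
  exceed 99%.
* **Half-life**: ordinary least squares of log intensity on time; under
  first-order decay the slope is -ln 2 / t-half. With four time points and
  multiplicative densitometry noise, OLS on logs is the standard, exactly
  testable estimator (a nonlinear fit would be the alternative; the source
  analyses do not state their method). Slopes at or above -1e-12 return a
  "no decay" sentinel — a flat curve carries float-noise slopes near zero —
  and the estimate is invariant to rescaling the loading-control
  normalisation.

# The synthetic generator

`simulate_methylome()` and `emit_counts()` produce data with the features
the analysis relies on:

* **Bimodal background.** Site levels come from a three-part mixture
  (weights 0.35 / 0.15 / 0.50): low Beta(1, 19), partial, high Beta(19, 1).
  The component is drawn per 500-bp tile and shared by the tile's sites,
  because methylation is regionally coherent — this is precisely why
  tile-level testing is meaningful. Partially methylated tiles draw a tile
  mean uniformly from [0.2, 0.8] and scatter their sites around it
  (Beta with concentration 30). Over 75% of background sites land below
  0.2 or above 0.8, reproducing the observed bimodality.
* **Monoallelic ICRs.** ICR sites carry the allele pair (1, 0). Reads are
  sampled allele-first — coverage splits Binomial(cov, 0.5) between alleles,
  each allele contributing reads at its own (conversion-adjusted) level —
  so observed ICR methylation is genuinely binomial around 50%, not a flat
  per-read coin.
* **Locus-driven coverage.** Each site has a Gamma(3, 3) coverage propensity
  shared by all samples; per-sample coverage is a shifted negative binomial
  (mean 30, dispersion 5, minimum 1) around it. RRBS depth is a property of
  the locus (MspI fragment structure), so deep sites are deep in every
  library. Without this, independently drawn coverage makes
  coverage-weighted tile percentages wobble between groups at any tile with
  residual level heterogeneity, inflating null tile-level test statistics —
  an artifact real RRBS does not exhibit.
* **Planted genotype effects.** mKO zeroes both ICR alleles and nothing
  else; KO subtracts 0.30 from DNMT3A-target tile sites (floored at 0) and
  leaves ICRs untouched; mzKO applies both. Target tiles (5% of CpG-bearing
  tiles, disjoint from ICR tiles) draw their WT levels from the methylated
  components only (30% partial in [0.5, 0.8], 70% high): the planted loss
  models moderate demethylation of regions that are methylated to begin
  with, and subtracting 0.30 from near-zero bimodal-low sites would plant
  no measurable effect. The 0.30 delta itself is a modelling choice — the
  source describes "moderate decreases" without an effect-size distribution.
* **Conversion failure.** Unconverted unmethylated cytosines read as
  methylated: the observed probability is
  `level + (1 - level) * conv_fail` with `conv_fail` = 0.005, and a matched
  non-CpG cytosine pool (20,000 per replicate) measures the failure rate;
  at 0.005 the QC rate is ~99.5%.

What the generator does **not** emulate: read-level structure (no FASTQ or
fragment simulation), MspI fragment boundaries and the resulting
covered-region geometry, SNPs and copy number, non-CpG methylation beyond
the QC pool, batch or library-size effects, and biological overdispersion
between replicates (replicates are true binomial draws from a shared level).
Passing tests therefore demonstrate that the pipeline recovers planted
structure under the stated statistical model, not that the model absorbs
every source of variation in real libraries — in real data the
no-overdispersion logistic test is anti-conservative at heterogeneous
units, which is exactly why calls also require a 25-point difference.

# Conventions and degenerate inputs

* Coordinates: Bismark coverage positions are 1-based; BED and genePred are
  0-based half-open; internally, site positions are 1-based and all
  intervals 0-based half-open, converted once at the boundary.
* The coverage file's percentage column is advisory; counts are
  authoritative, and disagreement beyond 0.5 points triggers a warning.
* CpG dyad strand calls are used as given; `destrand = TRUE` optionally
  merges (pos, pos + 1) pairs by summing counts. Whether the original
  extraction destranded before filtering is not stated; off is the default.
* Whether the original analysis pooled replicates or used the
  replicate-aware logistic path is not stated either; both are implemented,
  the choice is automatic (logistic whenever replicates exist) and recorded
  in the output's `test_method` attribute.
* Zero-coverage lines are dropped with a warning; duplicate sites are
  errors; empty inputs yield empty, well-typed outputs; unqualified units
  carry status `"unqualified"` with no p/q rather than being silently
  dropped.
* DM tables are written sorted with 6-decimal numeric formatting, so equal
  records produce byte-identical files and a write/read round trip
  reproduces records at that precision.

# Problem sizes

The default study simulates two 1.5-Mb chromosomes at ~80-bp CpG spacing
(~37,000 CpGs), 8 ICRs of 2 kb, 60 genes and 300 target tiles, with 3
replicates per genotype at 30x — enough for several thousand qualified
tiles per comparison while a full `run_study()` completes in seconds. The
test suite exercises the same pipeline on a 400-kb single-chromosome
variant (~5,000 CpGs, 6 ICRs), power checks on 2,000-site planted
comparisons, and oracle comparisons at the sizes stated in their tests
(BH up to n = 200, location assignment at 1,000 sites x 20 genes).

# Known limitations

* BH q-values, not SLIM; identical thresholds but not numerically identical
  adjusted values to analyses that used SLIM.
* No overdispersion or covariate adjustment; no beta-binomial model.
* Tile anchoring phase and the any-overlap tile annotation rule are
  conventions that can differ from other implementations.
* ICR refinement is a parameterised generalisation of two manual edits, not
  a published general rule.
* The half-life estimator reports a point estimate; curves that barely
  decay yield large, unstable estimates that should be read as bounds
  (e.g. "more than 12 h") rather than precise values.
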
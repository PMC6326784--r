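Package: methdiffr
Title: Differential DNA Methylation Analysis for RRBS Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Site- and tile-level differential DNA methylation analysis for
    reduced representation bisulfite sequencing (RRBS) count data in Bismark
    coverage format. Implements coverage-based site and 500-bp tile
    qualification, Fisher exact and binomial logistic likelihood-ratio tests
    with Benjamini-Hochberg adjustment, differential-methylation calling,
    methylation-state classification, strand-aware priority-ordered genomic
    annotation, imprinting control region (ICR) summaries and boundary
    refinement, cross-genotype concordance of hypomethylated and unchanged
    tiles, clone-based targeted bisulfite quantification, non-CpG conversion
    QC, and log-linear protein half-life estimation. A synthetic bisulfite
    count generator with planted genotype effects and ground-truth tables
    makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
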
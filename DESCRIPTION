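Package: canedet
Title: Count-Based Differential Transcriptome Analysis for BNF-Contrasting Sugarcane Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Differential-expression analysis of transcript read counts between two
    sugarcane genotypes with contrasting biological-nitrogen-fixation (BNF)
    efficiency, following the count-based recipe used for such designs: RPKM
    normalization, two-sided Fisher exact tests on pooled counts with Bonferroni
    family-wise error control, log2 fold changes, and a genotype-exclusive
    expression rule. Companion tools cover set algebra over DET lists (Venn
    partitions, same-direction intersections), hypergeometric term enrichment
    with Rich Factor, qPCR delta-Ct relative expression with dual reference
    genes, maximum-likelihood most-probable-number (MPN) estimation from serial
    dilution outcomes, assembly summary statistics, BLAST tabular filtering, and
    a negative-binomial simulator that generates the full 16-library design with
    planted ground truth for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
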
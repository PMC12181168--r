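Package: phenorank
Title: Paired Exercise-Training Transcriptomics with Phenotype-Correlated
    Gene Set Enrichment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired pre/post intervention bulk RNA-seq cohorts,
    built around resistance-training studies of young and older adults.
    Provides median-of-ratios normalization, paired differential expression
    with Benjamini-Hochberg correction and two-cohort overlap
    classification, hypergeometric over-representation analysis, and a
    subject-specific correlation stage that ranks genes by the Pearson
    correlation between per-participant log2 fold-changes and changes in
    muscle phenotypes (lean mass, strength, fiber size). Ranked lists feed
    a from-scratch pre-ranked GSEA with a gene-permutation null, normalized
    enrichment scores, FDR and leading-edge extraction. A negative-binomial
    cohort simulator with subject random effects and planted
    phenotype-coupled genes supports calibration and recovery testing
    without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    matrixStats,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    fgsea,
    readxl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
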
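Package: sqtlkit
Title: Splicing and Expression QTL Mapping with Local Genomic Relationship
    Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for mapping cis splicing QTLs (sQTLs), exon
    expression QTLs (eeQTLs) and gene expression QTLs (geQTLs) from
    genotype dosages and gene/exon/intron-junction count matrices.
    Builds exon inclusion and intron excision ratio phenotypes with
    rank-based normalisation, runs per-SNP cis regression scans with
    Storey q-values and a conjunction rule for calling sQTLs, tests
    differential splicing across tissues (mixed model) and between
    breeds, estimates cross-tissue genetic correlations by bivariate
    AI-REML on local genomic relationship matrices, combines signed t
    statistics across tissues in a one-degree-of-freedom meta-analysis,
    and tests set overlaps with Fisher's exact test. Includes a
    synthetic-data generator that plants known cis effects, LD, breed
    structure and cross-tissue genetic correlations so every stage can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    ggplot2,
    lme4,
    lmerTest,
    vcfR,
    rtracklayer,
    GenomicRanges,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
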
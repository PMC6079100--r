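Package: sortscreen
Title: FACS-Sorted CRISPR Screen Enrichment, BioID Differential Abundance,
    and Signature-Activity Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for reporter-sorted pooled CRISPR screens and
    their companion assays. Implements sgRNA counting from FASTQ,
    pseudocount normalization, sorted-versus-unsorted guide enrichment and
    gene-level redundant sgRNA activity (RSA) rank statistics with hit
    calling; label-free proteomics differential abundance with
    missingness-aware imputation (MinDet for intensity-dependent dropout,
    k-nearest-neighbour otherwise), quantile normalization and
    empirical-Bayes moderated t-statistics; per-sample Kolmogorov-Smirnov
    gene-signature activity scores with quartile stratification,
    Kaplan-Meier curves and log-rank tests; and genomic interval
    association statistics (summit classification, hypergeometric overlap
    enrichment, window-based peak-to-gene assignment, fragment-size
    stratification). A seeded synthetic-data generator reproduces the
    statistical structure of every input, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    survival,
    GenomicRanges,
    IRanges,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
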
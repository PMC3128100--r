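Package: fairechip
Title: Open Chromatin Analysis and GWAS Variant Prioritization for
    FAIRE Tiling Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-channel FAIRE (formaldehyde-assisted
    isolation of regulatory elements) tiling-array experiments: Tukey
    biweight between-channel scaling of log2 ratios, nucleosome-depleted
    region (NDR) detection with an iterative-threshold sliding-window peak
    caller, cross-condition and cross-cell-type peak concordance, genomic
    annotation of peaks against gene models, LD-proxy expansion of GWA
    index SNPs and intersection with cell-type-resolved NDRs, exact
    Wilcoxon rank-sum lineage enrichment, Spearman eQTL and knockout
    differential-expression screens, and construction of an
    expression-filtered first-order protein-interaction network. Includes
    a synthetic-data generator that emulates the probe tracks, gene
    models, LD panels, expression matrices and interactomes the pipeline
    consumes, so every stage is testable without array data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
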
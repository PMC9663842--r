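Package: sexomics
Title: Integrated Methylome and Transcriptome Analysis of Sex Differences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting and integrating sex
    differences in paired RNA-seq and whole-genome bisulfite sequencing
    data from a small balanced design (e.g. 6 males vs 6 females).
    Provides negative-binomial Wald differential expression with
    median-of-ratios normalization, signed weighted co-expression
    networks with k-means module refinement and a cross-sex Fisher
    exact test for differentially co-expressed modules, smoothed
    beta-binomial Wald testing of differentially methylated loci with
    rule-based region calling and genomic-context annotation,
    multiblock sparse PLS-DA discriminant integration of expression
    and per-region methylation with AUC evaluation, module-trait
    correlation, QTL-interval and term enrichment, phenotype
    comparison statistics, and a synthetic-data generator with planted
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    nortest,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    optparse,
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
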
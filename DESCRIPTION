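Package: enhancertrain
Title: Differential Enhancer Activity and GWAS Variant Enrichment for
    Paired Training Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for exercise-training studies of skeletal
    muscle regulatory elements. Identifies enhancers as H3K27ac consensus
    peaks supported by H3K4me1, tests paired pre/post differential
    H3K27ac and gene expression with per-feature negative binomial
    likelihood-ratio tests (~ participant + training), integrates scored
    enhancer-gene links into promoter groups and concordance statistics,
    and measures enrichment of genome-wide significant GWAS variants
    inside enhancer intervals against covariate-matched control SNPs
    using LD clumping, tag-SNP expansion with block-collapsed overlap,
    and logistic regression odds ratios. Includes a fully seeded
    synthetic-data generator emulating every input so the pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    MASS,
    data.table,
    IRanges,
    GenomicRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
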
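Package: quadmosaic
Title: Mosaic and De Novo Mutation Analysis in Quad-Family Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identification and characterisation of post-zygotic (mosaic)
    mutation from family-based whole-exome sequencing. Implements trio de novo
    calling with explicit depth, allele-support, genotype-likelihood and
    cohort-frequency filters; classification of de novo calls as mosaic or
    germline via a one-sided binomial test on the alternate-allele read
    fraction with Benjamini-Hochberg false-discovery control; read-backed
    phasing against nearby inherited heterozygous variants to confirm
    mosaicism, estimate the fraction of mutant cells and assign parental
    origin; validation-precision bookkeeping; per-exome mutation rates inside
    joint high-coverage regions with extrapolation to the capture target; a
    misclassification-aware model of the contribution of mosaic and germline
    de novo variation to diagnosis with beta-binomial credible intervals; and
    gene-length null models for recurrence and gene-set enrichment. A
    synthetic quad-family cohort generator with known truth labels makes every
    stage testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
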
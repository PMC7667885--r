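Package: chromaprime
Title: Differential DNase-Seq Accessibility Analysis of Primed and Inducible Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for differential chromatin accessibility
    analysis of DNase-Seq / ATAC-Seq cut-site data: pooled-summit window
    counting, median-of-top-peaks cross-sample normalization,
    replicate-consistent fold-change classification of cytokine-dependent
    primed and inducible open-chromatin sites, interval overlap and Venn
    partitioning against external peak sets, IUPAC consensus motif scanning,
    summit-to-summit proximity and nearest-gene analyses, tag-density
    profile matrices, and a negative-binomial synthetic cut-site generator
    with truth labels that makes every stage verifiable without sequencing
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    yaml,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
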
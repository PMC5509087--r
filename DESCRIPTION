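Package: genomewaves
Title: Time-Course Transcriptomic and Epigenomic Response Analysis with
    Regulatory Network Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for brain time-course RNA-seq and
    H3K27Ac ChIP-seq experiments with a treatment-by-time design. Provides
    TMM normalization and negative-binomial generalized linear models with
    a nested interaction formulation (~time + treatment:time) to identify
    genes whose temporal expression trajectory is altered by a treatment;
    Ward hierarchical clustering of temporal log2 fold-change profiles;
    mutual-information screening with prediction-error-gated regression to
    infer a transcriptional regulatory network; baseline and differential
    chromatin-accessibility calls from peak tag counts with truncated
    gene-domain assignment; and hypergeometric enrichment statistics that
    link the layers. A synthetic-data generator plants known temporal
    clusters, regulatory programs and accessibility changes so that every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    mclust
Config/testthat/edition: 3
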
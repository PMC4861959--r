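Package: rbpregulon
Title: Post-Transcriptional Regulatory Networks from RBP Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds RNA-binding protein (RBP) to target-transcript networks
    from CLIP-seq binding sites by mapping peaks into flanking windows
    around exon boundaries, classifies each RBP as significantly congruent
    (SC), significantly incongruent (SIC) or not significant (NSC) with
    respect to the tissue co-expression of its targets using matched-control
    resampling and rank-sum tests, models the features that explain the
    observed correlations (multivariate regression, backward stepwise
    elimination, elastic net) at the RBP-centric and transcript-centric
    levels, and compares protein-interaction network centralities between
    RBPs with concordant and discordant labels across expression levels.
    Includes a synthetic-data generator with planted network, correlation
    and centrality structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    glmnet,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
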
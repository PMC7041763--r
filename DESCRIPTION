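Package: cernaforge
Title: Competing Endogenous RNA Network Inference from Expression and
    Sequence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    networks from transcript models, sequences and small replicate count
    matrices. Covers candidate lncRNA filtering from assembled transcript
    models with an open-reading-frame coding-potential screen,
    negative-binomial exact-test differential expression with
    median-of-ratios normalization and Benjamini-Hochberg correction,
    miRNA binding-site scanning with a seed-weighted complementarity
    alignment and nearest-neighbor duplex free energies,
    correlation-thresholded pair inference, tripartite network assembly
    with a directional up/down/up dysregulation filter, and
    hypergeometric (optionally length-bias corrected) functional
    enrichment. Includes a synthetic-data generator with planted ceRNA
    triples so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
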
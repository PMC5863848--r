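Package: triohet
Title: Trio Transcriptomics and Heterosis Analysis for Parent-Hybrid Crosses
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of heterosis (hybrid vigour) in a two-parent / F1-hybrid
    trio from gene-level RNA-seq counts and phenotype tables. Converts counts
    to FPKM, performs negative-binomial differential expression with
    median-of-ratios normalization (usable with or without replicates),
    classifies every gene into the twelve additive / dominant / overdominant
    inheritance patterns, computes mid-parent, over-high-parent and
    low-parent heterosis indices for traits and per-gene expression, runs
    hypergeometric gene-set over-representation, and quantifies RNA-seq/qPCR
    concordance via the 2^-ddCt method. Includes a negative-binomial trio
    count simulator with planted inheritance modes so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
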
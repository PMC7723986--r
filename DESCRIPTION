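Package: lnclact
Title: Identification and Downstream Analysis of Long Non-Coding RNAs in a
    Two-Stage Lactation Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-usable pipeline for the downstream analysis of long
    non-coding RNAs (lncRNAs) from assembled transcript models in a small
    two-group RNA-seq design (lactation versus dry period, 2 vs 3 samples).
    Provides the candidate-lncRNA filter cascade (exon number, length, FPKM,
    annotation overlap, ORF-based coding potential), FPKM quantification,
    a conditional negative-binomial exact test for two-group differential
    expression, cis-window and co-expression trans target prediction,
    hypergeometric gene-set enrichment, export of lncRNA-gene regulatory
    networks, and 2^-ddCt qPCR concordance analysis. A seeded synthetic-data
    generator emulates every input with planted ground truth so each stage's
    recovery is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
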
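Package: solidfrac
Title: Hierarchical Classification and Differential Abundance of SOLiD
    Small RNA-Seq Reads from Blood Fractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of SOLiD color-space small RNA
    sequencing libraries from fractionated human blood (cells, plasma,
    16,000g and 160,000g plasma pellets, and vesicle-depleted
    supernatant). Implements di-base color-space encoding and decoding
    with csfasta/qual input and output, an iterative 3'-end trimming
    alignment ladder, three-tier hierarchical reference filtering with
    RNA-class assignment, per-library class-contribution tables, FPKM
    quantification with a minimum-alignment-count eligibility filter,
    and negative-binomial differential-distribution tests between blood
    fractions and between donor cohorts with upper-quartile
    normalization. A synthetic-data generator reproduces the library
    geometry and class mixtures the analysis assumes, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
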
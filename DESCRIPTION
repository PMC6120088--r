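Package: srnabias
Title: Benchmarking Ligation and Amplification Bias in Small RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying library-preparation bias in small RNA
    (miRNA) sequencing. Implements the equimolar-pool benchmark: per-miRNA
    fold-deviation from expected read counts, bias classification at a
    two-fold threshold, cross-kit differential quantification with false
    negative/false positive attribution, equal-depth subsampling detection
    curves, dilution-series concordance, and qPCR standard-curve absolute
    quantification. Includes a seeded library-preparation simulator
    (sequence-dependent ligation efficiencies, GC-dependent PCR
    amplification, adapter-dimer contamination) that provides ground truth
    for every analysis stage, an error-tolerant 3' adapter trimmer, and a
    reference-pool read counter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
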
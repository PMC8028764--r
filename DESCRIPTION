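Package: splitpool
Title: Simulation and Analysis of Split-Pool Combinatorially Barcoded
    Single-Cell RNA-Seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-species ("barnyard") split-pool barcoded
    single-cell transcriptomics. Provides a ground-truthed read simulator
    for combinatorial barcoding experiments (48 x 96 x 96 well barcodes
    across three rounds plus sub-library indices), read curation with
    quality, adapter, length and barcode-phase filters, whitelist-based
    cell-barcode extraction and error correction (hamming distance 1),
    unique k-mer gene assignment, UMI collapsing at edit distance 1 into
    per-species digital expression matrices, species-mixing QC with
    collision calling and doublet-rate calibration, read-downsampling
    saturation analysis, correlation-based label transfer against a
    reference atlas, and inference of RNA integrity numbers from the
    ribosomal fraction of electropherogram traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    S4Vectors,
    methods,
    data.table,
    pracma,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
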
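Package: mutassay
Title: Mutation-Rate, Mutation-Spectrum and Amplicon-Enrichment Analysis for
    Targeted In Vivo Mutagenesis Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for characterising targeted deaminase mutagenesis
    systems in microbial hosts. Estimates mutation rates from Luria-Delbruck
    fluctuation assays by Ma-Sandri-Sarkar maximum likelihood (with P0
    estimation and Stewart 95% confidence intervals); profiles per-position
    base-substitution spectra from quality-filtered targeted deep sequencing
    (pileup construction from minimal SAM, per-position frequencies, trimmed
    moving averages, windowed substitutions-per-base, fold enrichment with
    coordinate offsetting, background subtraction); demultiplexes barcoded
    amplicon reads into wells and calls significant mutations with a
    two-criterion (global-frequency OR replicate-count) rule including
    codon-effect annotation; and computes log-ratio growth rates from OD600
    time courses. Seeded synthetic-data generators with ground-truth
    bookkeeping emulate every input so each stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
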
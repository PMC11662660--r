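Package: sortscape
Title: Sort-Seq Deep Mutational Scanning Analysis for Anti-CRISPR Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for Flow-seq (sort-seq) deep mutational
    scanning of single-codon NNB saturation libraries: paired-end amplicon
    read merging and single-codon variant counting per FACS fraction,
    pseudocount and two-stage normalization into per-mutant fraction
    distributions, an affine regression model mapping fraction distributions
    to binned log-fluorescence histograms trained on individually measured
    benchmark mutants (closed-form ridge and zero-initialized gradient
    descent, leave-one-out cross-validation), per-variant inhibition
    potencies with cross-replicate confidence, and position-by-amino-acid
    mutational fitness landscape statistics. Includes a seeded synthetic
    experiment generator (truncated Gaussian-mixture fluorescence truths,
    multinomial FACS sorting and sequencing, FASTQ emission) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
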
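Package: tcsb
Title: Centrifugal Substitution Bias and mRNA Structure Analysis of
    Haplotype Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects directional weak/strong (AT/GC) mutation bias in
    synonymous sites of a mitochondrial coding gene. Builds a haplotype
    network under a parsimony criterion, orients every substitution
    centrifugally from the central to the peripheral haplotypes, tallies
    W/S direction spectra per group and compares them with an exact test
    (Test of Centrifugal Substitution Bias), computes class-partitioned
    sliding-window nucleotide diversity, predicts minimum-free-energy mRNA
    secondary structures across a temperature sweep under a compact
    nearest-neighbour thermodynamic model, and summarises structure
    distances as Fitch-Margoliash least-squares trees with a majority-rule
    consensus. Includes a fully ground-truthed synthetic haplotype
    generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
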
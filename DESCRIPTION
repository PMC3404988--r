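Package: trflpr
Title: In Silico T-RFLP Design, Kleptoplast Community Profiling and
    Amino-Acid Isotope Trophic Positions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling mixed chloroplast (kleptoplast) communities
    in sacoglossan sea slugs from terminal restriction fragment-length
    polymorphism (T-RFLP) of the chloroplast rbcL gene, and for estimating
    trophic position from compound-specific amino-acid nitrogen isotopes.
    Includes in silico PCR with IUPAC-degenerate primers, restriction
    digestion and terminal-fragment prediction, restriction-enzyme screening
    for clade discrimination, clone-library deduplication by p-distance and a
    half-sequence chimera screen, electropherogram peak quality control and
    relative-abundance profiling, a permuted Brunner-Munzel two-sample test
    for seasonal shifts, the glutamic-acid/phenylalanine delta-15N trophic
    position estimator, and seeded synthetic-data generators that emulate
    every input so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
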
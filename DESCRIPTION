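Package: peroxtyper
Title: Targeted Amplicon Recovery and Typing of Fungal Class II (AA2)
    Peroxidases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for targeted functional
    metagenomics of fungal class II peroxidases (CAZy auxiliary activity
    family AA2). Provides degenerate-primer representation and in-silico
    PCR (single-round and nested), conserved-region scanning and
    back-translation primer design, a mock-community amplicon read
    simulator with ground-truth labels, quality/length read filtering,
    dereplication and greedy 97 percent identity OTU clustering,
    six-frame translation with best-frame alignment to an ancestral
    lignin peroxidase reference, catalytic-residue calling at the
    E37/E41/W171/D183 framework positions, rule-based classification
    into manganese, versatile and lignin peroxidases, and stratified
    abundance reporting with Shannon diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    S4Vectors,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
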
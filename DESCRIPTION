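Package: modselsim
Title: Simulation-Based Performance Analysis of Phylogenetic
    Model-Selection Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how well the standard phylogenetic
    model-selection criteria (hierarchical likelihood-ratio tests, AIC,
    BIC, and decision theory) recover known nucleotide substitution
    models.  The package simulates alignments along birth-death and
    non-clock guide trees under the 24 fundamental GTR-family models
    (with invariable sites and discrete-gamma rate heterogeneity) and
    under the GY94 codon model, fits the full 56-model candidate set on
    neighbor-joining topologies, applies the four selection criteria,
    and summarises their accuracy, precision, pairwise dissimilarity,
    agreement profiles, and model biases, with chi-square homogeneity
    tests and randomized-block ANOVA/LSD comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    withr,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
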
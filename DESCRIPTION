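Package: ggrm
Title: Generalized Gametic Relationship Matrices for Parent-of-Origin Analyses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating imprinting (parent-of-origin) variance components
    in pedigreed populations. Builds the generalized gametic relationship matrix, a
    mixture of per-gamete effects for phenotyped individuals and per-individual
    transmitting abilities for the rest, constructs its sparse inverse directly from
    the pedigree, and derives a genomic counterpart from phased haplotypes that
    integrates ordered and unordered marker information. Fits the general weighted
    mixed model for parent-of-origin analyses by REML, with restricted
    likelihood-ratio tests against the Mendelian null, BLUP solutions for gametic
    effects and transmitting abilities, and a gene-dropping simulator for pedigrees,
    gametic effects, phenotypes and markers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
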
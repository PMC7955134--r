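Package: epiland
Title: Epistasis and Fitness-Pathway Landscapes from Combinatorial Mutant
    Deconvolutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies non-additive (epistatic) interactions among mutations
    from trait measurements of all 2^n intermediate genotypes between a parent
    and an n-site variant. Computes additive expectations with propagated
    standard errors, interaction magnitudes (epsilon), and the full
    sign/magnitude/reciprocal-sign epistasis taxonomy; derives kinetic traits
    (product formation rate, coupling efficiency, turnover frequency) and the
    regioselectivity free-energy transform RT*ln(p/(1-p)); enumerates all n!
    stepwise mutational orderings and classifies each pathway as favoured or
    disfavoured on one or several traits. Includes a seeded synthetic-landscape
    generator, a constraint-built example dataset for the P450 BM3
    testosterone-hydroxylation deconvolution, tidy tibble interfaces, ggplot2
    visualisations and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
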
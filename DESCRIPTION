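Package: cloneFluct
Title: Clonal Fluctuation Analysis of Reversible Anoikis Resistance
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Luria-Delbruck-style fluctuation analysis for acquired
    resistance to detachment-induced cell death (anoikis) in cancer cell
    populations. Implements a reversible two-state phenotype-switching
    branching model of the clone-expansion / suspension-assay protocol,
    closed-form relations between suspension survival, resistant fraction,
    growth rate and state memory, Monte Carlo prediction of interclonal
    fluctuation (coefficient of variation) under the two-state model,
    bootstrap confidence intervals for observed CVs, inter-passage
    regression, a geometric memory-decay model with least-squares fitting,
    and a heritable-continuum synthetic-data generator that reproduces the
    observed fluctuation structure. Includes a small command-line interface
    over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
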
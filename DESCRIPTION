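Package: qsarforge
Title: Descriptor-Based QSAR Model Building with Leave-One-Out Validation
    and Genetic-Algorithm Descriptor Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating small-n quantitative
    structure-activity relationship (QSAR) models from molecular descriptor
    tables: ordinary-least-squares fitting with the full set of diagnostics
    used in the QSAR literature (R-squared, standard error of estimate,
    F-statistic), leave-one-out cross-validation (Q2, PRESS), exhaustive and
    genetic-algorithm descriptor-subset selection, classical confidence and
    prediction bands for experimental-versus-predicted plots, potency unit
    arithmetic (IC50/pIC50) and kinase-panel selectivity summaries. Ships a
    worked imidazothiazole V600E-B-RAF/RAF1 kinase-inhibitor dataset and a
    synthetic-data generator for correlated descriptor pools with planted
    linear responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
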
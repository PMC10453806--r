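Package: bodycomp
Title: Cross-Validation of Field Body-Composition Methods in Young Athletes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to cross-validate field methods of body-composition
    assessment (skinfold prediction equations, bioimpedance fat-free-mass and
    total-body-water equations, air-displacement and underwater-weighing
    densitometry) against a three-compartment criterion model in young
    athletes. Provides an equation registry covering the classical skinfold
    and impedance equations, two- and three-compartment conversions (Siri,
    Brozek, Siri 3C), minimum-wrestling-weight certification arithmetic with
    weight-class accounting, a full method-agreement suite (Bland-Altman with
    proportional-bias regression, Lin's concordance correlation, standard
    error of the estimate, paired TOST equivalence, repeated-measures ANOVA
    with Holm-adjusted follow-ups, test-retest ICC), and a synthetic cohort
    generator that emulates the measurement structure of a mixed-sex athlete
    study for end-to-end pipeline testing and parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
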
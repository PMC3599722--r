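Package: markovquit
Title: Markov Chain Transition Models for Smoking Cessation Panels with
    Non-Ignorable Non-Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete-time two-state Markov chain models for longitudinal
    binary smoking-status panels. Fits paired logistic regressions for the
    cessation (smoking to abstinent) and relapse (abstinent to smoking)
    transitions from available consecutive observation pairs, and jointly
    models the outcome and non-response processes under a selection model
    for non-ignorable missingness, estimated by an EM algorithm that
    enumerates completions of the missing outcomes. Includes nonparametric
    bootstrap standard errors, crude transition matrices, Wald and F tests,
    odds ratios, BIC model comparison, and a synthetic-cohort simulator
    emulating a three-arm smoking-cessation trial design.
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
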
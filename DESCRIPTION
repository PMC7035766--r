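Package: fitradeoff
Title: Flexible and Interactive Tradeoff Elicitation for Multi-Criteria
    Choice Problems
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-criteria choice problems under an additive
    multi-attribute value model with partial information about the
    criteria scale constants.  Builds decision problems from
    questionnaire-style scores, normalizes consequences to a common
    scale, represents the weight space induced by a criteria ranking and
    by tradeoff statements, filters alternatives by potential optimality
    with linear programming, and drives a scripted, simulated or
    interactive elicitation session to a recommendation.  Ships a
    synthetic decision-maker simulator for validating the elicitation
    loop and a bundled emergency-triage protocol selection case study
    that exercises the whole pipeline.
License: MIT + file LICENSE
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
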
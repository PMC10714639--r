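Package: pdrcea
Title: Cost-Effectiveness Modelling of Proliferative Diabetic Retinopathy
    Treatment Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition model for the economic
    evaluation of panretinal photocoagulation (PRP) and intravitreal
    anti-VEGF injection in proliferative diabetic retinopathy (PDR).
    Implements four treatment strategies (PRP only, anti-VEGF only, PRP
    first, anti-VEGF first) over a lifetime horizon with health-state
    costs and utilities accrued from payer, healthcare-system, and
    societal perspectives; incremental cost-effectiveness analysis with
    dominance classification and efficiency frontiers; one-way
    deterministic sensitivity analysis (tornado diagrams); and
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves. Includes a vectorised microsimulation oracle
    for validating the cohort trace and synthetic-data generators for
    claims-like cost episodes, EQ-5D-like utility surveys, and a
    Gompertz baseline life table.
License: MIT + file LICENSE
Encoding: UTF-8
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
RoxygenNote: 7.3.3
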
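Package: psforage
Title: Producer-Scrounger Social Foraging: Simulation, Psychometric Scoring,
    and Nonparametric Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the producer-scrounger game in human social
    foraging. Provides a discrete-event agent-based emulator of a four-player
    virtual foraging task with costly probabilistic searches and joinable
    discoveries, closed-form rate-maximization predictions of the equilibrium
    producer proportion, the producer's index, scoring of the Big Five
    Inventory (44 items) and the Antisocial Process Screening Device (20
    items) including the stability and plasticity metatraits and the 12-point
    cutoff classification, and a nonparametric analysis pipeline (Shapiro-Wilk
    gate, Wilcoxon signed-rank, Mann-Whitney U, Pearson correlation matrix,
    case-resampling bootstrap confidence intervals) that renders the standard
    comparison and correlation tables.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
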
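Package: coloncea
Title: Markov Cohort Cost-Effectiveness Model of Adjuvant Chemotherapy for
    Colon Cancer
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Discrete-time Markov cohort model evaluating adjuvant
    chemotherapy strategies (CAPOX for 3 or 6 months, capecitabine for 6
    months, or no adjuvant therapy) after curative resection of high-risk
    stage II and stage III colon cancer in the South African public health
    system.  Converts survival curves, hazard ratios and abridged life
    tables into monthly transition probability schedules, simulates
    disease-free, recurrence and death states with time-since-recurrence
    tunnel substates and a half-cycle correction, and computes discounted
    costs, disability-adjusted life years, net monetary benefit and the
    cost-effectiveness frontier with extended dominance.  Includes one-way
    deterministic sensitivity analysis with tornado output and threshold
    search, probabilistic sensitivity analysis with beta, gamma and PERT
    parameter distributions and cost-effectiveness acceptability curves,
    subgroup and scenario re-parameterisations, and a synthetic-data
    generator that materialises complete runnable model configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
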
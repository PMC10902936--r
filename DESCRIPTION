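Package: pulpcea
Title: Markov Cohort Cost-Effectiveness Analysis of Pulpotomy Versus Root
    Canal Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling toolkit for comparing pulpotomy with
    root canal treatment in mature permanent teeth with irreversible pulpitis.
    Provides a discrete-time Markov cohort engine with age-dependent background
    mortality, tunnel states and discounted cost and tooth-life-year
    accumulation; the dental state-transition model with annual-failure-rate to
    per-cycle hazard conversion; a Gompertz-Makeham synthetic life table
    calibrated to a target remaining life expectancy; incremental
    cost-effectiveness ranking with dominance handling; one-way (tornado)
    sensitivity analysis; and Monte Carlo probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
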
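Package: feedcea
Title: Lifetime Cost-Effectiveness of Infant Feeding Modification via a
    Two-Part BMI Markov Cohort Model
Version: 0.1.0
Authors@R:
    person("Model", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-part, history-dependent Markov cohort model of body-mass-
    index (BMI) trajectories from birth to age 100 under two infant-feeding
    strategies (lower-protein versus higher-protein formula). The childhood
    model (ages 0-18) tracks annual transitions between normal weight,
    overweight, obese and dead, splitting the cohort by whether overweight or
    obesity was ever experienced; the adulthood model (ages 18-100) applies
    history-dependent mortality and accrues discounted costs and quality-
    adjusted life years. Includes transition-probability estimation from
    longitudinal category panels with interval-to-annual conversion,
    probabilistic sensitivity analysis (lognormal relative risks, gamma
    costs), incremental cost-effectiveness outputs (ICER, net monetary
    benefit, cost-effectiveness acceptability curves, averted person-years,
    population savings), an individual-level microsimulation for
    cross-validation, and a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
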
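Package: selcea
Title: Cost-Effectiveness Modelling of School-Based Socio-Emotional Learning Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition model for estimating the
    population-level costs and health impacts of scaling up universal and
    indicated school-based socio-emotional learning (SEL) programs that
    prevent depression/anxiety and suicide among adolescents. Provides a
    seeded synthetic-country generator (demography, epidemiology, enrolment
    and unit costs with the statistical structure the model assumes),
    cohort-component population projection, dependent-comorbidity
    combination of depression and anxiety epidemiology, standardized mean
    difference to relative risk effect-size conversion, healthy life year
    gained (YLL + YLD) burden accounting, staged intervention costing,
    average cost-effectiveness ratios standardized per million population,
    and an uncertainty toolkit: Monte Carlo uncertainty intervals,
    one-at-a-time deterministic sensitivity analysis, rank-correlation
    probabilistic sensitivity analysis and effect-size threshold analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
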
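Package: psmcea
Title: Partitioned-Survival Cost-Effectiveness Modelling for Oncology
    Treatment Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic modelling pipeline for cost-effectiveness
    analysis of second-line treatments in hormone-receptor-positive
    metastatic breast cancer: parametric survival extrapolation of
    progression-free and overall survival (exponential, Weibull, Gompertz,
    log-logistic), indirect comparison via hazard-ratio chains, a monthly
    three-state partitioned-survival cohort trace (pre-progression,
    post-progression, death), per-cycle cost and quality-adjusted life-year
    accrual with annual discounting, incremental cost-effectiveness and
    dominance analysis, one-way and scenario sensitivity analysis, and
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves. Includes a synthetic pseudo individual-patient
    data generator for exercising every stage without trial-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
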
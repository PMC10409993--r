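Package: nsclcCEA
Title: Cost-Effectiveness of First-Line Cemiplimab plus Chemotherapy in
    Advanced NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic pipeline for evaluating cemiplimab plus
    platinum-doublet chemotherapy against chemotherapy alone as first-line
    treatment of advanced non-small cell lung cancer, from the Chinese
    healthcare payer perspective. Implements pseudo individual-patient-data
    reconstruction from digitized Kaplan-Meier curves with numbers at risk,
    parametric survival extrapolation with AIC/BIC model selection,
    hazard-ratio scaling of Weibull survival laws, a three-state
    (progression-free / progressed / dead) cohort model on a 21-day cycle,
    cost and quality-adjusted life-year accrual with annual discounting,
    and deterministic (tornado), probabilistic (Monte Carlo with
    cost-effectiveness acceptability curves), price-threshold and subgroup
    uncertainty analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
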
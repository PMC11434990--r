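Package: mtxpoppk
Title: Population Pharmacokinetics of High-Dose Methotrexate in Pediatric
    Osteosarcoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects modelling of high-dose methotrexate
    (HDMTX) therapeutic drug monitoring data in pediatric osteosarcoma.
    Implements a two-compartment infusion model with covariate effects of
    serum creatinine on clearance and body surface area on central volume,
    between-subject and between-occasion variability, and proportional
    residual error; a Laplace (FOCE-I-style) population estimator with MAP
    empirical-Bayes individual estimates, stepwise covariate modelling and a
    nonparametric bootstrap; external-validation metrics (PE/MPE/MAPE/RMSE,
    F20/F30) with clinical acceptability rules; visual predictive checks and
    goodness-of-fit diagnostics; a synthetic cohort generator emulating a
    sparse pediatric TDM study design; and toxicity classification with
    leucovorin rescue recommendations under acute-kidney-injury scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    deSolve,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
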
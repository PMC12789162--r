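Package: micaux
Title: Minimal Important Change of Single-Item Measures via an Auxiliary PROM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates the minimal important change (MIC) of a single-item
    measure (SIM), such as a 0-10 numeric rating scale, by enriching a two-wave
    longitudinal confirmatory factor analysis (LCFA) with an auxiliary
    patient-reported outcome measure (AUX) that correlates with the SIM.
    Implements three AUX-enriched LCFA models fitted by diagonally weighted
    least squares on polychoric/polyserial correlations, the adjusted
    predictive modeling (APM) and LCFA MIC estimators, a calibrated generative
    simulator for SIM/AUX/transition-rating panels with present-state-biased
    anchors, and a Monte-Carlo performance study (bias, RMSE, Monte-Carlo
    standard errors) together with nonparametric bootstrap confidence
    intervals for single-dataset estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
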
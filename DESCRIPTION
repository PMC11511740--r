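Package: renopulse
Title: Coupled 1D-0D Pulse-Wave Haemodynamics of the Renal Circulation
    with Virtual Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates arterial pulse-wave propagation through a systemic
    arterial tree extended with bilateral intrarenal networks, using an
    explicit finite-volume solver for the 1D continuity and momentum
    equations with an elastic tube law, coupled to lumped R-C-R
    (Windkessel) outlet models. Provides generators for virtual ageing,
    diabetic and hypertensive populations, a brachial-pressure physiology
    filter, extraction of haemodynamic biomarkers (renal resistive index,
    mean renal blood flow, brachial pressures), Sobol sensitivity
    analysis, calibration utilities, and ROC/Youden evaluation of
    biomarker discrimination between diabetic and hypertensive
    nephropathy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    ggplot2,
    knitr
Config/testthat/edition: 3
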
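Package: crcuq
Title: Bayesian Calibration and Uncertainty Valuation for a Colorectal
    Cancer Microsimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A nine-state microsimulation of the natural history of
    colorectal cancer (the adenoma-carcinoma sequence), Bayesian calibration
    of its nine unknown parameters to age-specific epidemiological targets
    via incremental mixture importance sampling (IMIS), and a
    cost-effectiveness analysis of 10-yearly colonoscopy screening with
    probabilistic sensitivity analysis and per-patient expected value of
    perfect information under four characterizations of calibrated-parameter
    uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
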
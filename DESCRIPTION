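Package: physiofit
Title: Staged Fitting and Validation of Many-Parameter Physiological Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A framework for calibrating physiological models with many
    parameters against steady-state exercise data. Parameters are classified
    by their role in the model; fit candidates are screened by subset
    selection (SVD rank determination with pivoted QR on residual Jacobians)
    and by an error-weighted relative sensitivity analysis evaluated across
    stimulus levels and parameter perturbations; free parameters are then
    estimated in three sequential CMA-ES stages (base, specific, and
    stimulus-related) under a relative root-mean-square cost, and the result
    is validated with prediction-error, percent-change and settling-time
    metrics. Ships a compact cardiorespiratory demo model of incremental
    aerobic exercise and a synthetic cohort generator with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
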
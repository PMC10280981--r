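Package: npsmap
Title: Neuropsychiatric Subsyndromes, Cortical Thickness and White Matter
    Hyperintensity Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links neuropsychiatric subsyndromes to cortical thickness and
    white matter hyperintensity (WMH) burden across five disease cohorts
    (AD/MCI, ALS, FTD, PD, CVD). Implements NPI-Q subsyndrome scoring,
    head-size correction and log transformation of regional WMH volumes,
    contingency-table group comparisons, a repeated stratified train/test
    elastic-net procedure with lambda-consensus variable selection, and
    partial least squares correlation (PLSc) with stratified permutation
    tests and bootstrap-ratio stability analysis, together with a seeded
    synthetic cohort generator with plantable brain-behaviour effects for
    calibration and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
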
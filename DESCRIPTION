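Package: doseqa
Title: Patient-Specific QA Action Levels from 3D Dose Comparisons
Version: 0.1.0
Authors@R:
    person("doseqa", "developers", email = "doseqa@example.org",
           role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance of radiotherapy
    treatment plans by comparison of paired 3D dose distributions (a
    treatment-planning-system reference and an independent secondary dose
    calculation). Implements a global 3D gamma-index engine with a
    brute-force oracle, mean target dose difference, percentile-based
    action-level determination at controlled plan failure rates, the
    TG-218 action-interval formalism including truncated-distribution
    corrections for gamma pass rates, and a synthetic cohort generator
    emulating paired dose grids and result-level QA cohorts. Reads and
    writes DICOM RTDOSE and NRRD grids and CSV result tables, and ships a
    command-line pipeline that reproduces the full action-level study on a
    simulated cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
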
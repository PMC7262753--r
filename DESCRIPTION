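Package: careseg
Title: Need-Based Population Segmentation for Primary-Care Performance Reporting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies an adult population into four mutually exclusive
    need-based segments (low need, multiple morbidities, medically complex,
    frail) from administrative-claims-style tables, attributes patients to
    family physicians by plurality of ambulatory visits, computes cost, use
    and primary-care attribute measures (out-of-hours access, usual-provider
    continuity, coordination), and fits segment-stratified two-part cost
    models (logistic part one, log-link Gamma part two). Ships a synthetic
    claims generator with known ground truth so every stage is testable
    without access-restricted health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
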
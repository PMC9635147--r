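Package: asthmasteps
Title: Derive Asthma Treatment Steps from Electronic Prescription Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based derivation of asthma severity, by proxy of BTS/SIGN
    treatment steps, from electronic prescription records. Identifies asthma
    controller medications from free-text medication names, extracts dose
    frequency, dose quantity and medication strength from native dose
    instructions, imputes missing components by per-medication mode, bands the
    prescribed daily inhaled corticosteroid dose into low/medium/high/unknown
    categories, assembles treatment regimens over a 120-day lookback window at
    every prescription event, classifies each regimen to a treatment step via
    a configurable total decision tree, and summarises step trajectories
    (durations until step change with censoring, transition matrices,
    person-year summaries). Includes a synthetic prescription-record generator
    with known ground-truth trajectories so the full pipeline is testable
    without access to restricted health data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
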
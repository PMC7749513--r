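Package: ersplearn
Title: Classifying Go/NoGo Task Conditions from EEG Time-Frequency Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for discriminating Go versus NoGo task
    conditions from multi-subject EEG: group independent component analysis
    with equivalent-dipole screening, event-related spectral perturbation
    (ERSP) band-by-time features, a penalized single-hidden-layer neural
    network classifier selected by nested fivefold cross-validation, and
    bootstrap-validated hidden-unit signatures that localize
    condition-discriminating time-frequency perturbations. Includes a
    synthetic multi-subject EEG generator with planted, ground-truth spectral
    effects so that every stage of the pipeline can be validated against a
    known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
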
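Package: hatrial
Title: Target-Trial Emulation of Hearing-Aid Use and Dementia Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Emulates a hypothetical randomized trial of hearing-aid
    initiation in adults with incident hearing loss, using multi-source
    exposure and outcome ascertainment (self-report questionnaire pairs, a
    speech-in-noise threshold, dated electronic health-record codes), an
    explicit eligibility cascade, grace-period arm assignment, propensity
    weighting with covariate-balance diagnostics, doubly robust marginal
    risk ratios, inverse-probability-weighted Kaplan-Meier curves, weighted
    Cox models, and a sensitivity battery (E-values, negative outcome
    controls, healthcare-use adjustment). A synthetic electronic-health-record
    cohort generator with tunable confounding, detection-bias and
    diagnosis-dating mechanisms makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
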
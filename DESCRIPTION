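Package: GMOscreen
Title: Matrix-Approach qPCR Screening of GMOs with Unknown-Event Flagging
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements an extended TaqMan qPCR screening strategy for
    genetically modified organisms (GMOs) in feed and food samples: a
    validated assay-by-event specificity matrix over 32 screening methods
    (endogenous taxon genes, elements, constructs and the CaMV virus
    control), a deterministic eight-plate 96-well layout for 11 samples in
    duplicate with per-assay sensitivity and no-template controls,
    duplicate-well Cq calling into detected/not detected/suspect, and an
    inference engine that predicts candidate GMO events from detected
    elements, checks whether confirmed events explain every detected
    element, warns about masked events, and flags indications of unknown
    unauthorised GMOs. A synthetic Cq-data simulator with a Poisson
    single-copy dropout model makes the whole pipeline testable end to end,
    and per-sample sheets plus a cross-sample summary table provide a
    LIMS-ready export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
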
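Package: asbacklog
Title: Waiting-List Backlog Dynamics for Severe Aortic Stenosis Treatment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form dynamical-system model of an excess treatment
    waiting list that shrinks through surplus procedural capacity and
    pre-treatment mortality, applied to the post-pandemic backlog of severe
    aortic stenosis patients awaiting SAVR or TAVI in NHS England. Provides
    clearance-time and waiting-list-mortality solutions, capacity arithmetic
    for SAVR-to-TAVI conversion strategies, Monte-Carlo uncertainty
    propagation with 95% reference ranges, strategy grids and isoclines over
    the (conversion, capacity) plane, inverse capacity planning by root
    finding, and independent simulation oracles (daily-step Euler
    integration and a patient-level stochastic queue) for validating the
    closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
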
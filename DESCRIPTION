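Package: intergaze
Title: Social Utility, Attention, and Effort in Intergroup Allocation Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling and simulating intergroup allocation
    decisions with eye-tracking process data. Implements a discounted
    social-utility model in which the weight placed on an interaction
    partner's payoff is multiplicatively reduced for outgroup partners,
    scoring of the six-item Social Value Orientation slider measure, a
    dispersion-threshold (I-DT) fixation detector with area-of-interest
    dwell metrics and preregistration-style trial exclusion rules, a
    gaze-contingent attentional drift-diffusion simulator producing
    choices, response times and fixation sequences, a synthetic-experiment
    generator with known ground truth, and mixed-effects analyses of
    generosity, attention and decision effort together with a Monte Carlo
    simulation-based power procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
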
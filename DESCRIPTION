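Package: holddown
Title: Single-Unit Analysis of a Self-Paced Lever Hold-Down Task
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing extracellular single-unit recordings from
    mice performing a self-paced operant hold-down (action differentiation)
    task, in which reward is delivered at lever release only when the hold
    duration exceeds a session criterion. Provides validated containers for
    behavioral sessions and sorted spike trains, peri-event time histogram
    (PETH) construction with baseline-referenced modulation detection and
    z-scored epoch summaries, within-press duration-segment and
    duration-quartile firing dynamics, pseudo-population sliding-window
    decoding of press success with shuffled-label null distributions, outcome
    devaluation behavioral metrics, and a seeded generative model of task
    behavior and event-locked spiking (inhomogeneous Poisson by thinning)
    with recorded ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'behavior-metrics.R'
    'decoding.R'
    'holddown-package.R'
    'io.R'
    'params.R'
    'peth.R'
    'sessions.R'
    'press-dynamics.R'
    'simulate.R'
    'pipeline.R'
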
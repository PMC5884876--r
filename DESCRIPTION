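Package: iltk
Title: Adaptive Individual Lactate Threshold Testing Toolkit
Version: 0.1.0
Authors@R:
    person("Konstanz", "Exercise Lab Tools", email = "iltk@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for adaptive, lactate-guided
    incremental exercise testing. Provides a virtual-subject model of blood
    lactate and heart-rate kinetics around the maximal lactate steady state
    (MLSS), stateless detectors for the threshold criteria used in
    lactate-guided step tests (steep rise directly after a workload increment,
    delayed rise over up to eight constant-workload steps, and slow creep over
    at least three steps), a closed-loop protocol controller (warm-up,
    threshold adaptation, fine threshold adaptation, threshold detection and
    MLSS verification), study harnesses for test-retest reliability,
    increment-size effects and constant-velocity validation, and CSV/JSON
    session logging with a small command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
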
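Package: portalsim
Title: Biomechanics and Haptic Simulation of Arthroscopic Portal Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the forces involved in placing the
    posterior portal during shoulder arthroscopy. Generates synthetic
    operating-room trial recordings (synchronous 100 Hz force and optical
    marker streams with a three-phase force profile), preprocesses them
    (zero-phase low-pass filtering, shaft-projected travel distance, phase
    segmentation), estimates joint-capsule stiffness by through-origin least
    squares under Hooke's law together with peak puncture force and cohort
    summaries, characterizes device friction by an energy-conservation
    estimator on deceleration bench trials, and models a 1-DOF cable-driven
    haptic device (encoder quantization, penalty force rendering, sudden
    release at the puncture threshold, force saturation) whose replication
    fidelity is scored by the coefficient of determination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
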
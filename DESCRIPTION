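Package: prefgait
Title: Analysis of User-Preferred Prosthetic Ankle Stiffness from Gait,
    Metabolic, and Walking-Performance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying which measurable factors track a prosthesis
    user's preferred ankle stiffness. Implements steady-state metabolic rate
    estimation from breath-by-breath gas-exchange data under a piecewise
    constant condition schedule (first-order dynamic model solved by linear
    least squares), gait-cycle segmentation and stance detection from
    per-leg vertical ground reaction force, time-normalization of bilateral
    joint kinematics and kinetics with a registry of 25 biomechanical
    descriptors, and preference-normalized quadratic mixed-effects trend
    models with delta-method confidence intervals on the vertex stiffness.
    A synthetic-data generator emulates the full crossover study design
    (stiffness and speed grids, block trial schedules, stride-to-stride
    variability) with a ground-truth sidecar for recovery testing, and a
    pipeline driver runs simulation, estimation, descriptor extraction and
    trend inference end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
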
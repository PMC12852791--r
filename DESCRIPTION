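Package: optoloop
Title: Closed-Loop Optogenetic Microscopy Simulation and Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator for feedback microscopy: closed-loop
    feedback control of optogenetic cell biology without microscope hardware.
    Provides virtual optogenetic plants (a light-steerable migrating cell and a
    light-gated nucleocytoplasmic transport model), a virtual fluorescence
    microscope with patterned and pulse-width-modulated illumination, classical
    segmentation and nearest-neighbour tracking, trajectory-tracking and
    (gain-scheduled) PID controllers, and a closed-loop experiment runner with
    post-run metrics: path deviation, projected speed, corrected total cell
    fluorescence, one-phase-decay rate fits, and steady-state error estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    utils,
    grDevices,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png,
    knitr
Config/testthat/edition: 3
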
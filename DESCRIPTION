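Package: mouseutopia
Title: Agent-Based Simulation of Calhoun's Mouse-Utopia Experiment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A daily-step, individual-based birth-death-mating simulator of
    Calhoun's "mouse utopia" universe: a closed, resource-unlimited mouse
    population that grows exponentially and then collapses through the
    behavioral sink. Mortality follows a sex-specific parametric survivorship
    law converted to a daily hazard; reproduction is governed by mate
    readiness, Gaussian litter sizes, a sex ratio and an initial mating delay;
    overcrowding triggers deviation-factor decay, litter abandonment and
    permanent withdrawal of "beautiful ones" males. Includes calibrated
    phase-B parameter presets, the published experiment's anchor points, a
    squared-relative-deviation consistency metric for calibration, Monte-Carlo
    ensemble and time-to-size statistics, YAML configuration, CSV trajectory
    output with JSON run manifests, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
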
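Package: respsim
Title: Closed-Loop Simulation of Robot-Assisted Expiration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator of wearable robot-assisted expiration for
    respiratory rehabilitation research. Couples a single-compartment
    (resistance-elastance) lung model, a linear actuator-force to
    lung-pressure transmission model with per-subject calibration, a
    dual-layer assistive controller (phase-synchronised pressure profile
    generation with airway-pressure safety clipping, interaction-force
    feedback planning, and a PD plus nonlinear-feedforward supply-pressure
    tracking law), and a proportional-valve pneumatic plant with actuation
    lag. Includes a state-difference least-squares identifier for airway
    resistance and lung elastance from paired natural/assisted sessions,
    ventilation metrics (peak expiratory flow, tidal volume, minute
    ventilation with phase split), and a virtual-subject cohort generator
    for crossover protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
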
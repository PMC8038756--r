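Package: mfrelease
Title: Multifractal Release Kinetics for Polymer-Drug Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the controlled release of a covalently bound drug (an
    antifungal aldehyde on an imino-chitosan hydrogel) as scale-space dynamics
    governed by a Riccati-type gauge. Provides closed-form oscillatory
    solutions with regime classification and bifurcation-style scans,
    kink/antikink (tanh) and logistic release laws with analytic inverses,
    the SL(2,R) operator algebra with its joint invariants linking scale
    space to laboratory time, nonlinear least-squares calibration of release
    and fungal-kill curves against classical dissolution models (zero-order,
    first-order, Higuchi, Hixson-Crowell, Korsmeyer-Peppas), seeded synthetic
    data generators, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
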
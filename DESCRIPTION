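Package: p2dsensor
Title: Pseudo-Two-Dimensional Reaction-Diffusion Modelling of Heterogeneous
    Nanozyme Glucose Biosensors
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Coupled diffusion of glucose and hydrogen peroxide across a
    quiescent boundary layer over a laterally heterogeneous catalytic surface,
    with Michaelis-Menten surface kinetics confined to the sensor plane.
    Provides a uniform one-dimensional reference model and a pseudo-2D
    finite-volume solver (steady and transient), extraction of effective
    (apparent) kinetic parameters, diffusion-layer and response-time metrics,
    colorimetric and amperometric readout proxies, sensor calibration metrics
    (limit of detection, linear range), parameter sensitivity sweeps, and a
    validity calculator for the pseudo-2D scale-separation assumptions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
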
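Package: ohmicheat
Title: Coupled Electro-Thermal Simulation of Ohmic Pasteurization of Solid Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ohmic (Joule) pasteurization of a homogeneous solid
    cylindrical food. The quasistatic electrical potential is solved with a
    temperature-dependent conductivity, the resulting volumetric Joule source
    drives a transient axisymmetric finite-volume heat balance with insulated
    or Newton-cooling boundaries, and first-order thermal inactivation
    kinetics (D-, z- and F-values) are integrated per cell to locate the cold
    spot and the time to a target log reduction. Ships the measured
    mashed-potato property table used for model development, the seven
    process-sensitivity scenarios (heat-loss coefficient, ambient
    temperature, electrical conductivity perturbations), constant-voltage
    and constant-power drive modes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
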
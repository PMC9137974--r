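Package: anklekin
Title: Biaxial Ankle Kinematics, Draw-Wire Trilateration and Joint Axis
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the human ankle as a two-revolute-axis
    (talocrural and subtalar) joint. Implements product-of-exponentials
    forward kinematics from screw-theoretic twists, an analytic tetrahedral
    trilateration solver that recovers a foot platform's three vertices and
    pose from seven draw-wire sensor lengths, and a least-squares axis
    estimation pipeline (plane fit, in-plane circle fit, median aggregation,
    sagittal-plane intersection, Pluecker line coordinates). A draw-wire
    sensor chain model (resistance, amplification, ADC quantization,
    calibration, EWMA filtering) and a seeded synthetic capture generator
    replace the measurement hardware for simulation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
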
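Package: braidfe
Title: Elastic Property Prediction for 3D-Braided Fiber-Reinforced Meniscus Implants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts the linear-elastic behaviour of a three-dimensionally braided,
    Kevlar-reinforced polycarbonate-urethane (PCU) meniscus implant. Implements
    bridging-model micromechanics for matrix-impregnated fiber bundles, an
    eight-node hexahedral finite-element kernel with embedded bar reinforcement,
    periodic-boundary-condition homogenization of representative volume cells, a
    parametric generator of the layered braided crescent lattice, and a macro-scale
    comparison of the braided implant against a pure-matrix implant under
    physiological compressive loads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
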
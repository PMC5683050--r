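Package: nervestretch
Title: Yeoh Hyperelastic Modelling of Peripheral-Nerve Stretch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the uniaxial stretch response of peripheral
    nervous tissue with a reduced (I1-only) Yeoh strain energy function.
    Provides the closed-form incompressible uniaxial Cauchy stress, Drucker
    stability screening, species presets spanning pig, rabbit, lobster and
    Aplysia nerves, constrained quasi-Newton identification of the material
    constants from stress-stretch curves with sensitivity and correlation
    statistics, a synthetic multi-extension curve generator, specimen geometry
    reduction (elliptic cylinder to area-equivalent circular cylinder to
    axisymmetric slice), and a displacement-driven finite-element solver for
    fully incompressible hyperelasticity (mixed displacement-pressure, 3-D
    hexahedral and 2-D axisymmetric) with theory-versus-simulation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
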
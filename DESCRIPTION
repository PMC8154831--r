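Package: skinphase
Title: Multilayer Biphasic Finite-Element Model of Human Skin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuum poroelastic modelling of human skin as a stack of
    biphasic layers (epidermis, papillary and reticular dermis, hypodermis,
    muscle). Each layer couples a fiber-reinforced, exponentially stiffening
    solid with an osmotically pre-swollen interstitial fluid moving by Darcy
    flow with deformation-dependent permeability. The package ships the
    per-layer material table, a swelling equilibrium solver, a homogeneous
    material-point driver for uniaxial tension and relaxation, and a mixed
    displacement/chemical-potential nonlinear finite-element solver on 3-D
    hexahedral and axisymmetric meshes, with protocol runners for ex vivo
    uniaxial tension/relaxation and in vivo suction, layer tension and
    tangent-stiffness extraction, fluid particle tracing, and least-squares
    parameter fitting on synthetic tension-stretch curves.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo, RcppEigen
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
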
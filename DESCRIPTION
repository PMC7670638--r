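Package: mreatlas
Title: Desk-Scale Brain Magnetic Resonance Elastography Atlas Pipeline
Version: 0.1.0
Authors@R: person("MRE", "Atlas Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses brain magnetic resonance elastography (MRE)
    studies at desk scale. Provides digital viscoelastic brain phantoms and
    synthetic cohorts, time-harmonic shear-wave forward simulation on voxel
    grids, octahedral-shear-strain quality control, direct and subzone-based
    nonlinear inversion to the complex shear modulus, shear-stiffness and
    damping-ratio map computation, affine spatial normalization with
    template-space atlas averaging, and region-of-interest statistics using
    general linear mixed models with an unstructured covariance matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    truncnorm,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppEigen
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
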
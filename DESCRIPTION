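Package: fascicleMF
Title: Microstructure Fingerprinting of Crossing White-Matter Fascicles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dictionary-based estimation of per-fascicle white-matter
    microstructure (fascicle volume fractions, fiber volume fraction and
    extra-axonal diffusivity) from multi-shell diffusion MRI in voxels with
    crossing fascicles. Implements the exhaustive combinatorial
    Microstructure Fingerprinting estimator built on non-negative least
    squares together with two accelerated estimators: a hybrid method that
    projects the signal onto all rotated dictionary atoms with a single NNLS
    and maps the weights to tissue parameters with a split-arm multilayer
    perceptron, and a fully-learned method that feeds per-shell real
    even-degree spherical-harmonics coefficients to a network that jointly
    predicts tissue parameters and fascicle orientations. Includes PGSE
    acquisition-scheme tools, an analytic cylinder-and-tensor fingerprint
    generator with a reduced-fidelity Monte Carlo cross-check, a synthetic
    voxel simulator with Rician-style noise, and an evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    pracma,
    S4Vectors,
    SummarizedExperiment,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
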
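Package: dpkchain
Title: Machine-Learned Dose Point Kernels and Voxel Dosimetry for Beta
    Emitters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for internal dosimetry with beta-emitting radionuclides.
    Generates scaled dose point kernels (sDPKs) for monoenergetic electron
    point sources with a calibrated synthetic shell-scoring emulator or from
    imported Monte Carlo tables, fits multi-target regressor chains with
    ridge, lasso, or elastic-net base models to predict sDPKs from material
    composition and source energy, synthesizes beta-emitter kernels from
    emission spectra, builds voxel dose kernels by Monte Carlo volume
    integration, computes absorbed-dose maps by FFT convolution of cumulated
    activity, and validates dose distributions with a 3D gamma index and
    per-region statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
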
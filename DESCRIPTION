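Package: opmsim
Title: Simulation of OPM Sensor-Array Designs for MEG Source Localization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation framework for comparing on-scalp optically pumped
    magnetometer (OPM) array designs with a fixed channel count. Builds
    192-channel monoaxial, biaxial and triaxial sensor arrays on a
    half-ellipsoid head surface, computes current-dipole leadfields in a
    homogeneous spherical volume conductor, simulates dipolar MEG signals
    contaminated by sensor noise, distributed brain noise and
    movement-induced ambient-field interference, applies a set of
    interference-suppression methods (baseline subtraction, harmonic field
    correction, tSSS, DSSP, adaptive multipole modeling, LCMV beamforming),
    fits equivalent current dipoles and summarizes localization error and
    dipole-moment recovery per array design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
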
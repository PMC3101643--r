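Package: edmlasso
Title: Sparse Estimation of Conformational Variability in Electron-Density Space
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Distinguishes genuine conformational variability from coordinate
    noise in a crystallographic ensemble by working in electron-density-map
    (EDM) space. The density of a base conformer is expressed as an
    L1-regularized (Lasso) linear combination of the densities of ensemble
    members; members whose coefficients shrink to zero are classified as
    truly variable, while members with statistically significant weights are
    noise variants of the base. Includes a P1 electron-density and
    structure-factor engine (Gaussian atoms, FFT map synthesis, R/R-free), a
    synthetic two-conformer crystal simulator with labeled ensembles, a
    coordinate-descent Lasso solver with regularization paths and
    cross-validated penalty selection, per-residue sliding-window profiles,
    and baseline RMSD/B-factor comparators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
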
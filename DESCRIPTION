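Package: xcwfit
Title: X-ray Constrained Wavefunction Fitting and Electron-Density Similarity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits X-ray constrained restricted Hartree-Fock (XC-RHF) wavefunctions
    against theoretical structure-factor amplitudes and quantifies how much of the
    electron-correlation signature of a correlated one-particle density the
    constrained single determinant recovers. Ships a self-contained Gaussian-basis
    electronic-structure backend (McMurchie-Davidson integrals, restricted
    Hartree-Fock, determinant-based CISD/FCI), analytic Fourier transforms of
    atomic-orbital pair densities on a P1 pseudo-crystal reciprocal lattice, the
    chi-squared-penalised self-consistent field solver with warm-started
    constraint-weight scans, QTAIM bond-critical-point searches, and a suite of
    real-space electron-density similarity indicators (topological agreement
    index, real-space R, Carbo distance, RMSD/MAD, attachment/detachment
    densities).
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
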
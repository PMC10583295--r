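Package: rpdlf
Title: Simulation and Time-Domain Fitting of R-PDLF NMR Dipolar Modulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Numerical simulation of proton-detected local-field (PDLF)
    solid-state NMR experiments that use R18(1,7) symmetry-based
    heteronuclear dipolar recoupling under magic-angle spinning, with
    explicit integration over the radio-frequency (B1) spatial
    inhomogeneity of the probe coil.  Time-domain chi-square fitting of
    one- and two-component dipolar modulations extracts C-H bond order
    parameter magnitudes with profile-likelihood confidence bounds.
    Includes pre-computed modulation databases over grids of order
    parameters, frequency-domain utilities for dipolar splitting read-off
    and order-parameter conversions (1H-13C dipolar and 2H quadrupolar),
    nutation-based estimation of the RF inhomogeneity profile, and a
    deterministic synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
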
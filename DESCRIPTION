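Package: fccs
Title: Simulation and Analysis of Dual-Color Fluorescence
    Cross-Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dual-color fluorescence cross-correlation
    spectroscopy (FCCS) as used to quantify protein-protein interactions
    in live cells. Includes a Brownian-dynamics generator of two-channel
    photon-count traces (point emitters diffusing through co-aligned 3D
    Gaussian detection volumes, with Poisson photon statistics, spectral
    crosstalk, background and triplet blinking), direct and
    quasi-logarithmic ("multi-tau" grid) correlation estimators with
    segment-based uncertainties, weighted nonlinear fitting of one- to
    three-component 3D diffusion models with an optional triplet factor,
    structure-parameter calibration from a reference dye, the relative
    cross-correlation amplitude (RCA) interaction statistic with bound
    fractions, and group comparison by Student's t-test. A reproducible
    pipeline ties the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
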
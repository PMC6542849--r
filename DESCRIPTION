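Package: porenoise
Title: Ion Sizing from Sub-Nanopore Conductance and Current-Noise Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for measuring de-hydrated ion sizes from electrolytic
    point-contact (sub-nanopore) recordings. Implements activity-corrected
    electrolyte models (extended Debye-Hueckel and Truesdell-Jones),
    bi-conical pore geometry and occupancy estimates, point-contact and
    reduced-order conductance models with a steric-modified
    Poisson-Boltzmann radial solver, power-spectral-density estimation and
    decomposition of voltage-clamp current noise into pink (1/f), white and
    dielectric components, correlated-carrier threshold detection with
    two-stage extrapolation of threshold currents to ion diameters, a
    synthetic-data generator with planted ion sizes, and a one-dimensional
    Brownian-dynamics ion-permeation simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
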
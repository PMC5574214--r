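Package: ipadflow
Title: Arterial Pulse Waves and Intramural Periarterial Drainage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coupled modelling of cerebral arterial pulse-wave propagation and
    intramural periarterial drainage (IPAD) of interstitial fluid through
    arterial basement membranes. Solves the one-dimensional compliant-vessel
    blood-flow equations on the middle cerebral artery and its first
    bifurcation (Richtmyer two-step Lax-Wendroff scheme, three-element
    Windkessel outlets), maps the resulting pressure and wall-displacement
    fields into the arterial wall with a thick-walled-cylinder elasticity
    approximation, and evolves the basement-membrane thickness with a
    lubrication-reduced Darcy model whose permeability switches with the sign
    of the axial pressure gradient (a valve). Includes a synthetic Doppler
    waveform generator with Fourier peak-averaging, a two-dimensional annular
    Darcy reference solver, cycle-averaged drainage metrics, valve-ratio and
    wall-position sweeps, and reverse-flow threshold location by bisection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    jsonlite,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
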
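Package: tmsbem
Title: Charge-Based Boundary Element Modelling of TMS-Induced Electric Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasistatic electric field modelling for transcranial magnetic
    stimulation (TMS) in multi-compartment surface head models using a
    charge-based boundary element method. The induced surface charge density
    on tissue conductivity interfaces is obtained from a second-kind Fredholm
    integral equation, discretized with piecewise-constant charges on
    triangulated interfaces, with analytic near-field triangle integrals.
    Both an iterative (GMRES, matrix-free) and a direct (factorize-once,
    many right-hand-sides) solution path are provided, together with
    synthetic nested multilayer-sphere head models, parametric
    figure-of-eight coils, an analytic spherically-symmetric-conductor
    reference solution, field reconstruction, boundary-condition audits and
    error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    pracma,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
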
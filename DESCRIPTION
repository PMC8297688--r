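Package: atrialcv
Title: Conduction-Velocity-Driven Parametrization and Simulation of Atrial
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate conduction-velocity (CV) fields from atrial
    activation maps by local tangent-plane projection and degree-two polynomial
    least squares, to translate CV into heterogeneous anisotropic conductivity
    and CV-dependent ionic remodeling of the Courtemanche-Ramirez-Nattel (CRN)
    human atrial cell model, to solve the resulting monodomain reaction-diffusion
    system with linear finite elements and backward differentiation formulae
    (orders 1-3) with segregated ionic coupling and state-variable interpolation,
    and to analyze induced reentrant activity: activation maps, dominant
    frequencies, phase-singularity (rotor) detection and tracking, and S1-S2
    vulnerable-window scans. Synthetic substrates (structured tissue sheets,
    paroxysmal-like and persistent-like conduction-velocity fields, eikonal
    activation maps) make the whole pipeline runnable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    rlang,
    tibble,
    dplyr,
    purrr,
    xml2,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    arrow
Config/testthat/edition: 3
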
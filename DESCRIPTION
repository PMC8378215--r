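Package: nozzleflow
Title: In Silico Nozzle Flow and Shear-Stress Screening for Extrusion Bioprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Steady laminar flow of power-law (shear-thinning) hydrogel bioinks
    through parameterized conical and blunted print nozzles. Provides the
    closed-form power-law Poiseuille solution, a quasi-1D lubrication solver
    with kinetic-energy correction, and a 2D axisymmetric finite-volume
    (SIMPLE) solver; constrained maximin Latin-hypercube design-of-experiments
    campaigns over nozzle geometry; a Gaussian-process surrogate with
    main-effect curves and Sobol sensitivity indices of the maximum shear
    stress; and a literature-derived shear-stress versus cell-viability
    linkage for blunted-nozzle printing conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    lhs,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
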
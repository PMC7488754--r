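Package: synaptodyn
Title: Delay-Differential Dynamics of FMRP-Dependent Local Translation at the
    Activated Synapse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring the dynamical regimes of a three-variable
    delay-differential model of local protein synthesis at an activated
    glutamatergic synapse, in which the pool of active membrane receptors is
    maintained both by FMRP-controlled de novo synthesis and by endosomal
    recycling. Provides a fixed-step Runge-Kutta integrator for the delayed
    Cauchy problem with dense history interpolation, Poincare sections and
    crossing sets, regime classification (zero, stationary, periodic,
    quasi-periodic, chaotic) combining crossing-cluster structure with a
    twin-trajectory sensitivity criterion, multi-start attractor censuses,
    one-parameter bifurcation scans with branch tracking and transition
    bracketing, and regime-table summaries over parameter grids. Results are
    returned as tibbles and plotted with ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
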
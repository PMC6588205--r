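Package: tumourflow
Title: Coupled Vascular and Interstitial Fluid Transport on Whole-Tumour
    Microvascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates blood flow and interstitial fluid transport across
    explicit, segmented tumour microvascular networks. Vascular blood flow is
    modelled as Poiseuille flow with an empirical in vivo effective-viscosity
    law, and unknown boundary conditions are estimated by constrained
    optimisation against target pressures and wall shear stresses.
    Interstitial flow follows a Darcy description solved by superposition of
    regularized Green's function point sources distributed along the
    vasculature, coupled to the vascular compartment through Starling's law
    of transvascular filtration. Includes stochastic surface boundary
    assignment calibrated to tissue perfusion, convex-hull and sphere-packing
    perfusion estimation, radial profiling, parameter-sensitivity sweeps,
    vascular-normalization therapy scenarios, seeded synthetic-network
    generators, and independent finite-difference validation oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
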
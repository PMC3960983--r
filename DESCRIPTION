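Package: amdpmf
Title: Accelerated Molecular Dynamics Boost Potentials and Free-Energy
    Landscape Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for accelerated molecular dynamics (aMD)
    enhanced sampling and potential-of-mean-force (PMF) analysis. Implements
    the aMD boost potential, modified forces and the dual-boost parameter
    recipe used for membrane-protein simulations; a Langevin simulator on
    analytic toy potentials with optional boost; reaction-coordinate
    extraction (atom-pair distances, side-chain chi1/chi2 dihedrals) from PDB
    structures and trajectory frames, including the ionic-lock and
    toggle-switch coordinates of GPCR activation; and 1D/2D PMF estimation
    with multi-bin-size precision sweeps, exponential Boltzmann reweighting
    and cumulant-expansion reweighting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
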
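Package: bindkin
Title: Association Kinetics and Free-Energy Landscapes from Coarse-Grained
    Binding Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate protein-peptide association rates from
    ensembles of coarse-grained binding trajectories. Bound states are
    defined by an inter-molecular bead-contact criterion, first passage
    times are extracted per trial and converted to bimolecular rate
    constants via the one-molecule-per-box concentration, with bootstrap
    uncertainties, exponential-distribution fits and Welch tests between
    conditions. Trajectories are projected onto (RMSD, centre-of-mass
    distance) collective variables, Gaussian-kernel densities are
    Boltzmann-inverted into potential-of-mean-force landscapes, and
    receptor radius-of-gyration ensembles are decomposed into Gaussian
    mixtures. A synthetic overdamped Brownian-dynamics generator (rigid
    two-domain receptor with a tunable linker, rod-like charged ligand,
    Debye-Hueckel screened electrostatics in a periodic box) provides
    trajectories with the statistical structure the estimators assume,
    together with Smoluchowski and Debye-Smoluchowski closed-form rate
    oracles for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    mclust,
    jsonlite,
    bio3d,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
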
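Package: chitomc
Title: Coarse-Grained Constant-pH Monte Carlo Simulation of Chitosan in Solution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-site-per-monomer model of chitosan polysaccharides in aqueous
    solution. Chains are rigid pyranose monomers whose only flexible degrees of
    freedom are the glycosidic dihedrals (phi, psi), sampled by pivot-move
    Metropolis Monte Carlo from two-dimensional free-energy maps restricted at a
    configurable energy cutoff. Non-bonded interactions are a purely repulsive
    (WCA) Lennard-Jones term and Debye-Hueckel screened electrostatics; the
    protonation state of glucosamine monomers is sampled in a semi-grand
    canonical ensemble at constant pH, swapping the dihedral maps of adjacent
    links whenever a monomer's charge changes. Includes map loading/synthesis
    and feature analysis, radius-of-gyration and bond-correlation estimators,
    persistence-length decomposition into intrinsic and electrostatic parts,
    Benoit-Doty and Odijk-Houwaart worm-like-chain estimators, and modified
    Henderson-Hasselbalch titration-curve fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
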
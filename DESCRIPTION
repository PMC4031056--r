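Package: aggtraj
Title: Aggregation Analysis of Multi-Copy Protein Simulation Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying protein self-association in
    multi-copy molecular simulation trajectories. Detects intermolecular
    atomic contacts under periodic boundaries, classifies oligomeric states
    as connected components of the molecular contact graph, measures
    association and dissociation kinetics against the Smoluchowski
    diffusion-limited reference, computes solvent-accessibility-normalized
    per-residue interaction propensities (Shrake-Rupley SASA), foldedness
    metrics (backbone RMSD by Kabsch superposition, alpha-helical residue
    counts by the Kabsch-Sander hydrogen-bond rules, hydrophobic-core
    packing distances), and cutoff Lennard-Jones plus reaction-field
    Coulomb energy decompositions with an aggregated-versus-monomeric
    potential-energy-difference estimator. Includes a Brownian-dynamics
    simulator of diffusing sticky molecules with known association and
    dissociation rates and ground-truth event and energy logs, so that
    every analysis stage can be validated against planted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    yaml,
    knitr
Config/testthat/edition: 3
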
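Package: ligmode
Title: Binding-Mode and Rotamer Geometry Analysis of Ligand-Receptor
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trajectory-geometry toolkit for classifying ligand
    alkyl-chain binding modes and receptor side-chain rotamer states in
    molecular-dynamics trajectories of G-protein-coupled receptors.
    Computes signed torsion angles, aromatic ring centroids,
    atom-to-centroid distance series, Kabsch superposition and ligand
    heavy-atom RMSD; classifies chain dihedrals into minus/plus
    anticlinal (L-shape/I-shape) modes and chi1 angles into t/g+/g-
    rotamers; summarises occupancy, dwell times and circular statistics;
    and quantifies chain-rotamer coupling with contingency tables, odds
    ratios, Cramer's V and mutual information, plus distance gating
    against a threshold. A coupled Markov/von Mises synthetic-trajectory
    generator emits matched series, 3-D coordinates and multi-model PDB
    files so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
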
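Package: confdock
Title: Conformational Diversity Analysis and Ensemble Docking for Drug-Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether a small-molecule binding site sits in a
    rigid or mobile region of a flexible protein, and for docking a ligand
    against every deposited conformer of that protein. Implements Kabsch
    superposition and pairwise C-alpha RMSD over a conformer ensemble,
    identification of the maximum-diversity conformer pair, per-residue
    displacement Z-score profiles with a binding-site flexibility verdict,
    ensemble re-docking orchestration with a pluggable engine contract and
    affinity aggregation, ligand pose and substructure RMSD comparison,
    protein-ligand contact and hydrogen-bond detection, and a drug-likeness
    panel (molecular weight, Crippen logP, hydrogen-bond donors/acceptors,
    rotatable bonds, Ertl topological polar surface area) with Lipinski and
    Veber verdicts. Includes seeded generators for synthetic conformer
    ensembles and protein-ligand complexes with known ground truth.
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
    ggplot2,
    jsonlite,
    yaml,
    generics,
    bio3d,
    Biostrings,
    igraph,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
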
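Package: dynopharm
Title: Dynamic Structure-Based Pharmacophores from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds structure-based pharmacophore models from protein-ligand
    molecular dynamics trajectories and validates them by virtual screening.
    Perceives pharmacophore features on ligands and interaction-capable groups
    on protein residues, detects frame-wise interactions with configurable
    geometric rules, computes interaction occurrence tables and unique-model
    histograms, merges the most frequent per-frame models into per-ligand and
    final consensus models with exclusion volumes, and screens multi-conformer
    small-molecule libraries against the models with ROC/AUC and enrichment
    factor validation. Includes a synthetic-data generator that emulates a
    C4-symmetric channel-pore binding site with prescribed per-frame
    interaction occupancies and property-matched decoy libraries, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineR,
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
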
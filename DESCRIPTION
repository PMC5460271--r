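Package: lectinet
Title: Dynamical Network and Coevolution Analysis of Bulb-Type Lectin
    Dimer Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how bulb-type (mannose-binding)
    lectin monomers recognise each other to form dimers. Classifies residues
    of a dimer complex into interface, surface, interior and ligand-binding
    sites from solvent-accessible surface area (Shrake-Rupley sampling),
    builds weighted dynamical residue networks from trajectory motion
    correlations restricted to persistent contacts, computes closeness,
    betweenness, characteristic path length and delta path length with
    z-score flagging, performs mean-field direct coupling analysis (direct
    information) on single- and double-domain lectin alignments, and runs a
    hydrophobic-polar interaction-pattern resampling at interface positions.
    Ships synthetic generators (correlated-Gaussian trajectories, Potts-model
    alignments, toy dimers) with machine-readable ground truth so every stage
    is testable without molecular dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    seqinr,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
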
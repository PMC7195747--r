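Package: dpdfrag
Title: Molecular Fragment Dissipative Particle Dynamics Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preparation, simulation and evaluation toolkit for molecular
    fragment dissipative particle dynamics (DPD). Parses particle-set files
    (particle types, pairwise repulsions, amino-acid fragment tables) and
    SPICES molecular line notations, converts PDB peptide/protein structures
    to coarse-grained particle models, builds simulation-box start
    configurations at correct DPD density with sphere/layer/cuboid
    compartments, integrates the DPD equations of motion with harmonic bonds,
    movement constraints and restartable runs, and evaluates trajectories
    (temperature and energy series, radial distribution functions, radii of
    gyration, nearest-neighbor censuses, axis frequency histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    bio3d,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
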
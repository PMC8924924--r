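Package: poserank
Title: Rescoring Docked Protein-Ligand Poses with a Directional
    Message-Passing Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for ranking docked protein-ligand poses with a
    directional message-passing graph network whose continuous-filter
    convolutions use spherical Bessel radial kernels. Includes
    symmetry-corrected ligand RMSD and hit/gap/miss pose labeling,
    cross-docking group construction (receptor superposition, binding-site
    clustering, representative capping), Uniprot and sequence-similarity
    train/test splits, pose and compound enrichment metrics, and a
    synthetic-complex generator so the full pipeline is exercisable at
    desk scale without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    Biostrings,
    ChemmineR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
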
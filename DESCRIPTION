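Package: cyslock
Title: Cysteine-Anchored Covalent Virtual Screening and Modification Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Covalent virtual screening at nucleophilic cysteines by exhaustive
    torsion-scan docking of Michael-acceptor ligands, scored with Coulomb
    electrostatics and the Lennard-Jones 6-12 potential. Includes pocket
    extraction and parameterization from PDB structures, warhead detection and
    the covalent Michael-addition transform, systematic conformer enumeration,
    library screening with top-fraction selection, trajectory frame clustering
    by C-alpha RMSD (k-medoids with occupancies and medoid representatives), a
    cysteine-conservation alignment screen, covalent-adduct mass validation
    (elemental formulas, tryptic digestion, adduct matching), and NMR
    chemical-shift-perturbation classification. Deterministic synthetic-data
    generators provide desk-scale pockets, ligand libraries, trajectories and
    peak lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    cluster,
    igraph,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
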
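Package: gwfold
Title: Lattice Protein Folding with a Group-Weighted Contact Potential
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ab initio protein folding simulation on the face-centred-cubic
    (FCC) lattice. Conformations are self-avoiding walks in a relative
    direction encoding; a genetic algorithm with exhaustive pull-move,
    diagonal-move, rotation and crossover operators, elitist selection and
    random-walk stagnation recovery searches for minimum-energy structures.
    Search guidance uses a 20x20 pairwise contact potential, either directly
    or after a non-uniform "group-weighted" rescaling that amplifies the
    separation between high- and low-magnitude contact energies. Includes
    the hydrophobic-polar (HP) potential as a comparator, distance-matrix
    RMSD against native alpha-carbon coordinates, relative-improvement and
    speed-up metrics, and a bundled benchmark set of 17 protein sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
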
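Package: hpfold
Title: Local Search for HP-Model Protein Structure Prediction on the
    Face-Centered Cubic Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simplified protein structure prediction on the face-centered
    cubic (FCC) lattice under the hydrophobic-polar (HP) energy model.
    Implements a tabu-style local search over single-monomer moves with two
    stagnation-control devices: a long-term memory of visited local minima,
    stored as compact canonical conformation encodings and queried by Hamming
    proximity, and an elite archive of runner-up conformations that the
    search retreats to when it stalls.  Includes exact self-avoiding-walk
    enumeration with lattice-symmetry reduction for small chains (used as an
    optimality oracle), conformation codecs (absolute and first-occurrence
    canonical direction encodings with 4-bit packing), amino-acid to H/P
    classification, FASTA input, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
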
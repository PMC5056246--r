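Package: parasymd
Title: Internal Symmetry Detection in Protein Structures by a Parallel
    Alignment Scan
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects internal (rotational and screw) symmetry in
    single-chain protein structures. The CA trace is aligned against
    circularly permuted copies of itself at every offset from 1 to N-3;
    each offset is refined by iterating weighted Kabsch superposition
    with a monotone structure-based sequence alignment, scored by a
    weighted count of aligned residues (T-score) and standardized to a
    Z-score across offsets. The symmetry (screw) axis is decomposed from
    the best transformation. A master-worker parallel scan distributes
    offsets across worker processes with automatic load balancing and
    produces results identical to the serial scan. Includes generators
    for Cn-symmetric toy structures and random-coil negative controls.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    MASS,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
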
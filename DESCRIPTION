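Package: soludel
Title: Three-Body Delaunay Buriedness Scoring for Solubility Mutagenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts whether point mutations increase or decrease protein
    solubility from a coarse-grained structural model. Each residue is
    reduced to its side-chain center, the Delaunay tessellation of the
    centers defines three-body contacts, and a combinatorial buriedness
    classification (nine classes for triangles, four for edges) separates
    surface from buried contacts without any surface-area computation.
    Surface triplets (buriedness classes 0-4) carry a log-likelihood
    potential estimated from a structure set; mutation scores are weighted
    sums of potential changes, with per-triplet-type weights in [0,2]
    trained by a max-margin linear program. Includes cross-validation
    (leave-one-out, k-fold, folds-from-file) with accuracy, Matthews
    correlation and per-class precision, a hydrophobicity-window baseline,
    and synthetic structure/mutant generators with brute-force oracles for
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    boot,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
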
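Package: bsptools
Title: Conserved-Block Detection, Classification and Phylogeny of Binder of
    Sperm (BSP) Superfamily Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the Binder of Sperm (BSP) protein superfamily:
    degenerate-pattern scanning for the nine conserved sequence blocks of the
    tandem fibronectin type II (FN2) architecture, assembly and validation of
    the two-domain architecture including disulfide topology, family
    classification (BSP, BSPH1, BSPH2) from diagnostic block fingerprints,
    nearest-reference BSP subfamily assignment, from-scratch neighbor-joining
    phylogeny with pairwise-deletion Dayhoff PAM distances and bootstrap
    supports, gene-neighborhood (synteny) pattern matching, annotation
    reconciliation against proposed nomenclature, and a seeded synthetic
    sequence/neighborhood generator with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
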
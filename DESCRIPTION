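Package: srcrtools
Title: Annotation, Phylogenetics and Nomenclature of SRCR-Superfamily
    Receptors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments multi-domain scavenger receptor cysteine-rich (SRCR)
    proteins such as CD163 and WC1 into group-B SRCR domains, characterizes
    each domain's eight-cysteine scaffold, aligns domain cores with a
    Gonnet-250 affine-gap aligner, estimates pairwise p-distances with
    bootstrap standard errors, builds neighbor-joining trees with bootstrap
    support, assigns each domain a nomenclature letter by clade placement
    against labelled reference domains, derives domain-architecture strings
    and receptor family-type calls, and scans cytoplasmic tails for the
    WC1-type tyrosine signalling motif.  A seeded simulator generates
    receptor families with full ground truth (domain coordinates, letters,
    architecture, tree, motifs) so every stage can be benchmarked without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
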
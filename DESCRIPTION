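Package: gtclan
Title: Family Building for Divergent Polysaccharide Polymerase
    Glycosyltransferases
Version: 0.1.0
Authors@R:
    person("gtclan", "developers", email = "gtclan@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying extremely divergent
    sugar-diphospholipid-utilizing glycosyltransferases (bacterial
    polysaccharide polymerases, Wzy-type) into families.  Implements a
    two-stage clustering pipeline (a sequence similarity network at a
    strict bit-score threshold followed by profile-profile comparison of
    the resulting clusters), an alignment-based hierarchical tree
    algorithm built on distance-geometry embedding and nearest-neighbour
    joining, and a backbone similarity score for the oligosaccharide
    repeat units polymerized by these enzymes, including inference of the
    retaining/inverting reaction stereochemistry from the polymerase
    bond.  Seeded synthetic-data generators provide ground-truth protein
    families, glycan repeat units and hierarchical point clouds for
    testing the whole stack without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    Biostrings,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
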
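Package: afpvote
Title: Antifreeze Protein Identification and Ice-Binding Residue Voting from
    Sequence Compositions
Version: 0.1.0
Authors@R:
    person("afpvote", "maintainers", email = "afpvote@example.org",
           role = c("aut", "cre"))
Description: Identifies antifreeze proteins (AFPs) from primary sequence
    alone using an ensemble of radial-basis-kernel support vector
    classifiers, one per n-peptide composition coding scheme (contiguous,
    partitioned, g-gap dipeptide and sliding-window compositions over the
    original and reduced physicochemical amino-acid alphabets).  A genetic
    algorithm prunes each scheme's feature attributes, a jury vote combines
    the per-scheme verdicts into a sequence-level AFP call, and matches of
    the selected attributes are mapped back onto residues to flag candidate
    ice-binding positions without requiring a 3D structure.  Includes
    evaluation metrics (per-class accuracy, precision, Matthews correlation
    coefficient), global-alignment sequence-identity analysis, a synthetic
    planted-motif benchmark generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
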
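Package: mulsel
Title: Hierarchical Reduction, Alignment and Visualisation of Large Sequence Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reduces very large, diverse protein (or recoded nucleotide)
    sequence families to a small representative alignment. Combines a fast
    alignment-free presort based on common k-peptide counts with cascades of
    span-limited profile/profile mini-alignments, selecting one representative
    per mini-alignment using length-deviation and annotation penalties. Ships
    an artificial acid-rich family generator and reversed-sequence
    (doppleganger) harness for validating segregation, and a coloured
    alignment visualiser with conservation-averaged panels and secondary
    structure, transmembrane and RNA stem-loop tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
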
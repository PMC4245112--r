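Package: cladesearch
Title: Maximum-Parsimony Search and Clade Support for Morphological
    Character Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equally-weighted maximum-parsimony analysis of discrete
    morphological character matrices with mixed unordered (Fitch) and
    ordered (additive/Wagner) characters. Provides TNT- and NEXUS-style
    matrix input/output, exact branch-and-bound and random-addition TBR
    heuristic tree searches with monophyly constraints, zero-length-branch
    (rule 1) collapsing, strict consensus, ensemble consistency and
    retention indices, Bremer decay indices via converse-constraint
    searches, bootstrap resampling with absolute and GC group frequencies,
    a character-simulation module with known generating trees, and a
    one-call driver that reproduces a complete published-style analysis.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
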
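#' Hand-checkable six-taxon fixture with a verified results card
#'
#' A fixed 6-taxon x 10-character matrix (one ordered character, one
#' polymorphic cell, missing entries) whose complete expected results -
#' optimal length, the unique most-parsimonious tree, ensemble fit indices
#' and per-clade decay indices - were established by exhaustive enumeration
#' over all 105 six-leaf topologies and are shipped alongside the data, so
#' that every pipeline stage can be checked against known values.
#'
#' @return list with `matrix` (a [character_matrix()]) and `expected`:
#'   `length`, `mpt_newick` (character vector of the collapsed MPTs),
#'   `CI`, `RI`, `CI_informative`, `RI_informative`, and `decay`, a named
#'   vector keyed by `+`-joined clade members.
#' @export
fixture_small <- function() {
  tokens <- rbind(
    a = c("1", "1", "0", "0", "0", "0", "0", "0", "01", "0"),
    b = c("1", "1", "0", "0", "0", "0", "1", "0", "0",  "0"),
    c = c("0", "0", "0", "?", "0", "1", "0", "1", "0",  "0"),
    d = c("0", "0", "1", "1", "0", "1", "1", "1", "1",  "0"),
    e = c("0", "0", "1", "1", "1", "2", "0", "0", "1",  "0"),
    f = c("0", "?", "1", "1", "1", "2", "1", "0", "1",  "1"))
  m <- character_matrix(tokens, taxa = letters[1:6],
                        char_type = c(rep("unordered", 5), "ordered",
                                      rep("unordered", 4)))
  expected <- list(
    length = 14,
    mpt_newick = "(a,b,(c,(d,(e,f))));",
    CI = 11 / 14, RI = 0.75,
    CI_informative = 10 / 13, RI_informative = 0.75,
    decay = c("e+f" = 1L, "d+e+f" = 1L, "c+d+e+f" = 2L))
  list(matrix = m, expected = expected)
}
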
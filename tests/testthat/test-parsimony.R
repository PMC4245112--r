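test_that("single-character lengths match hand and oracle values", {
  t4 <- parse_newick("((A,B),(C,D));")
  expect_equal(char_length_unordered(t4, c(A = "0", B = "0", C = "1", D = "1")), 1L)
  # 0101 needs two steps: confirmed by the exhaustive-assignment oracle
  expect_equal(brute_force_char_length(ape::unroot(t4), c("0", "1", "0", "1")), 2L)
  expect_equal(char_length_unordered(t4, c(A = "0", B = "1", C = "0", D = "1")), 2L)
  expect_equal(char_length_unordered(t4, c(A = "?", B = "?", C = "?", D = "?")), 0L)
  # ordered: 0,2,0,2 costs 4 (oracle: 4), unordered view costs 2
  col <- c(A = "0", B = "2", C = "0", D = "2")
  expect_equal(brute_force_char_length(ape::unroot(t4), col, "ordered"), 4L)
  expect_equal(char_length_ordered(t4, col), 4L)
  expect_equal(char_length_unordered(t4, col), 2L)
  # two-taxon distance is forced through any tree
  expect_equal(char_length_ordered(t4, c(A = "0", B = "2", C = "?", D = "?")), 2L)
})

test_that("character lengths equal the exhaustive assignment minimum", {
  set.seed(406)
  for (i in 1:30) {
    n <- sample(4:6, 1L)
    tr <- ape::rtree(n, br = NULL, tip.label = letters[1:n])
    tok <- random_tokens(n, 1L, n_states = 3L)[, 1L]
    names(tok) <- letters[1:n]
    expect_equal(char_length_unordered(tr, tok),
                 brute_force_char_length(tr, tok, "unordered"),
                 label = sprintf("unordered case %d", i))
    expect_equal(char_length_ordered(tr, tok),
                 brute_force_char_length(tr, tok, "ordered"),
                 label = sprintf("ordered case %d", i))
    expect_gte(char_length_ordered(tr, tok), char_length_unordered(tr, tok))
  }
})

test_that("tree length agrees with phangorn on clean matrices", {
  set.seed(407)
  for (i in 1:8) {
    n <- sample(5:8, 1L)
    tr <- ape::rtree(n, br = NULL, tip.label = letters[1:n])
    tok <- matrix(as.character(sample(0:2, n * 12L, TRUE)), n, 12L,
                  dimnames = list(letters[1:n], NULL))
    m <- character_matrix(tok, taxa = letters[1:n])
    pd <- phangorn::phyDat(tok, type = "USER", levels = c("0", "1", "2"))
    expect_equal(tree_length(tr, m)$total_length,
                 phangorn::parsimony(tr, pd, method = "fitch") |> as.numeric())
    # ordered characters against phangorn's sankoff with linear costs
    m_ord <- character_matrix(tok, taxa = letters[1:n], char_type = "ordered")
    costs <- outer(0:2, 0:2, function(a, b) abs(a - b))
    dimnames(costs) <- list(c("0", "1", "2"), c("0", "1", "2"))
    expect_equal(tree_length(tr, m_ord)$total_length,
                 phangorn::parsimony(tr, pd, method = "sankoff",
                                     cost = costs) |> as.numeric())
  }
})

test_that("length is invariant to rooting and to taxon row order", {
  set.seed(408)
  m <- random_char_matrix(7L, 15L)
  tr <- ape::rtree(7L, br = NULL, tip.label = letters[1:7])
  L <- tree_length(tr, m)$total_length
  expect_equal(tree_length(ape::unroot(tr), m)$total_length, L)
  expect_equal(tree_length(ape::root(tr, "d", resolve.root = TRUE),
                           m)$total_length, L)
  perm <- sample(7L)
  m2 <- character_matrix(m$tokens[perm, ], taxa = m$taxa[perm],
                         char_type = m$char_type, weights = m$weights)
  expect_equal(tree_length(tr, m2)$total_length, L)
})

test_that("per-character minima and star maxima follow their definitions", {
  expect_equal(min_steps(c("0", "0", "1", "2")), 2L)
  expect_equal(min_steps(c("0", "0", "1", "2"), "ordered"), 2L)
  expect_equal(min_steps(c("?", "?", "?", "?")), 0L)
  expect_equal(max_steps_star(c("0", "0", "1", "1")), 2L)
  expect_equal(max_steps_star(c("0", "0", "1", "2"), "ordered"), 3L)
  # uninformative column: g == m == 1
  expect_equal(min_steps(c("0", "0", "0", "1")), 1L)
  expect_equal(max_steps_star(c("0", "0", "0", "1")), 1L)
  # polymorphism resolves best-case: {0,1} can sit with either state
  expect_equal(min_steps(c("01", "0", "1", "1")), 1L)
  # star-tree length computed on the actual star topology agrees with g
  set.seed(409)
  for (i in 1:10) {
    n <- sample(4:7, 1L)
    tok <- random_tokens(n, 6L)
    star <- ape::read.tree(text = paste0("(", paste(letters[1:n],
                                                    collapse = ","), ");"))
    for (type in c("unordered", "ordered")) {
      m <- character_matrix(tok, taxa = letters[1:n], char_type = type)
      s <- tree_length(star, m)$per_char
      g <- apply(tok, 2L, max_steps_star, char_type = type)
      expect_equal(s, unname(as.integer(g)))
    }
  }
})

test_that("m <= s <= g on random trees and columns", {
  set.seed(410)
  for (i in 1:25) {
    n <- sample(4:8, 1L)
    tr <- ape::rtree(n, br = NULL, tip.label = letters[1:n])
    type <- sample(c("unordered", "ordered"), 1L)
    tok <- random_tokens(n, 1L)[, 1L]
    names(tok) <- letters[1:n]
    s <- char_length_one <- if (type == "ordered") {
      char_length_ordered(tr, tok)
    } else {
      char_length_unordered(tr, tok)
    }
    expect_lte(min_steps(tok, type), s)
    expect_lte(s, max_steps_star(tok, type))
  }
})

test_that("ensemble CI and RI follow their definitions", {
  # single character with m = 1, s = 2: CI = 0.5
  t4 <- parse_newick("((A,B),(C,D));")
  m1 <- character_matrix(matrix(c("0", "1", "0", "1"), 4L, 1L),
                         taxa = LETTERS[1:4])
  fs1 <- fit_statistics(m1, tree_length(t4, m1))
  expect_equal(fs1$CI, 0.5)
  # a homoplasy-free matrix on its generating tree: CI = RI = 1
  tr <- parse_newick("((a,b),(c,(d,(e,f))));")
  splits <- list(c("a", "b"), c("d", "e", "f"), c("e", "f"))
  tok <- vapply(splits, function(g) as.character(as.integer(letters[1:6] %in% g)),
                character(6L))
  m2 <- character_matrix(tok, taxa = letters[1:6])
  fs2 <- fit_statistics(m2, tree_length(tr, m2))
  expect_equal(fs2$CI, 1)
  expect_equal(fs2$RI, 1)
  # fixture card, established by exhaustive enumeration
  fx <- fixture_small()
  mpt <- parse_newick(fx$expected$mpt_newick)
  fs3 <- fit_statistics(fx$matrix, tree_length(mpt, fx$matrix))
  expect_equal(fs3$CI, fx$expected$CI, tolerance = 1e-12)
  expect_equal(fs3$RI, fx$expected$RI, tolerance = 1e-12)
  expect_equal(fs3$CI_informative, fx$expected$CI_informative,
               tolerance = 1e-12)
  # all-constant matrix: CI undefined, flagged as NA
  m4 <- character_matrix(matrix("0", 4L, 3L), taxa = LETTERS[1:4])
  fs4 <- fit_statistics(m4, tree_length(t4, m4))
  expect_true(is.na(fs4$CI))
  # diagnostics table is 1-based and consistent
  di <- character_diagnostics(fx$matrix, tree_length(mpt, fx$matrix))
  expect_identical(di$index, seq_len(fx$matrix$n_char))
  expect_true(all(di$m <= di$s & di$s <= di$g))
})

test_that("weights multiply a character's contribution", {
  fx <- fixture_small()
  m <- fx$matrix
  tr <- parse_newick(fx$expected$mpt_newick)
  s7 <- tree_length(tr, m)$per_char[7L]
  m3 <- character_matrix(m$tokens, taxa = m$taxa, char_type = m$char_type,
                         weights = replace(m$weights, 7L, 3L))
  expect_equal(tree_length(tr, m3)$total_length,
               fx$expected$length + 2L * s7)
})
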
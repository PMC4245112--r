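test_that("degenerate simulation settings behave as documented", {
  tr <- parse_newick("((a,b),(c,(d,e)));")
  # zero change probability: all columns constant, zero length on any tree
  sim0 <- simulate_matrix(tr, n_char = 12L, edge_prob = 0, seed = 1L)
  expect_true(all(apply(sim0$matrix$tokens, 2L,
                        function(col) length(unique(col)) == 1L)))
  other <- parse_newick("((a,c),(b,(d,e)));")
  expect_equal(tree_length(other, sim0$matrix)$total_length, 0)
  # full missingness: every cell '?', zero length on any tree
  sim1 <- simulate_matrix(tr, n_char = 6L, edge_prob = 0.3,
                          missing_fraction = 1, seed = 2L)
  expect_true(all(sim1$matrix$tokens == "?"))
  expect_equal(tree_length(other, sim1$matrix)$total_length, 0)
  expect_error(simulate_matrix(tr, 5L, edge_prob = 1.2, seed = 1L),
               "edge_prob")
  expect_error(simulate_matrix(tr, 5L, seed = NULL), "seed")
})

test_that("simulation is deterministic given the seed", {
  tr <- parse_newick("((a,b),(c,(d,e)));")
  s1 <- simulate_matrix(tr, 20L, edge_prob = 0.2, missing_fraction = 0.2,
                        seed = 33L)
  s2 <- simulate_matrix(tr, 20L, edge_prob = 0.2, missing_fraction = 0.2,
                        seed = 33L)
  expect_identical(s1$matrix$tokens, s2$matrix$tokens)
})

test_that("homoplasy-free realizations give CI = RI = 1 on the true tree", {
  # a realization is homoplasy-free exactly when every character's realized
  # change count equals its number of distinct tip states minus one
  set.seed(417)
  found <- 0L
  for (i in 1:150) {
    tr <- random_topology(letters[1:8])
    sim <- simulate_matrix(tr, n_char = 25L, edge_prob = 0.02,
                           state_counts = 4L, seed = 418L + i)
    distinct <- apply(sim$matrix$tokens, 2L,
                      function(col) length(unique(col)))
    if (!all(sim$changes == distinct - 1L)) next
    fs <- fit_statistics(sim$matrix, tree_length(sim$truth, sim$matrix))
    if (is.na(fs$RI)) next
    found <- found + 1L
    expect_equal(fs$CI, 1)
    expect_equal(fs$RI, 1)
    if (found >= 3L) break
  }
  expect_gte(found, 3L)
  # the true tree never scores worse than a random tree
  set.seed(419)
  for (i in 1:15) {
    tr <- random_topology(letters[1:8])
    sim <- simulate_matrix(tr, n_char = 40L, edge_prob = 0.05,
                           seed = 500L + i)
    rand <- random_topology(letters[1:8])
    expect_lte(tree_length(sim$truth, sim$matrix)$total_length,
               tree_length(rand, sim$matrix)$total_length)
  }
})

test_that("per-edge change probabilities target the intended branches", {
  set.seed(420)
  tr <- random_topology(letters[1:10])
  ep <- edge_change_probs(tr, internal = 0.5, pendant = 0)
  sim <- simulate_matrix(tr, n_char = 60L, edge_prob = ep, seed = 421L)
  # pendant branches never change, so the two leaves of any cherry always
  # carry identical states
  po <- ape::reorder.phylo(sim$truth, "postorder")
  nt <- length(po$tip.label)
  kids <- split(po$edge[, 2L], po$edge[, 1L])
  for (ch in kids) {
    tips <- ch[ch <= nt]
    if (length(tips) == 2L) {
      rows <- match(po$tip.label[tips], sim$matrix$taxa)
      expect_identical(sim$matrix$tokens[rows[1L], ],
                       sim$matrix$tokens[rows[2L], ])
    }
  }
})

test_that("the fixture card is exactly what exhaustive enumeration gives", {
  fx <- fixture_small()
  m <- fx$matrix
  expect_equal(m$n_taxa, 6L)
  expect_equal(m$n_char, 10L)
  tops <- enumerate_topologies(letters[1:6])
  lens <- vapply(tops, function(tr) tree_length(tr, m)$total_length,
                 numeric(1L))
  expect_equal(min(lens), fx$expected$length)
  mpts <- tops[lens == min(lens)]
  expect_length(mpts, 1L)
  expect_identical(split_signature(mpts[[1L]]),
                   split_signature(parse_newick(fx$expected$mpt_newick)))
  # decay per clade re-derived from the enumeration
  taxa <- letters[1:6]
  for (key in names(fx$expected$decay)) {
    grp <- strsplit(key, "+", fixed = TRUE)[[1L]]
    lacking <- vapply(tops, function(tr) {
      !any(vapply(bipartitions(tr), setequal, logical(1L), grp))
    }, logical(1L))
    expect_equal(min(lens[lacking]) - min(lens),
                 as.numeric(fx$expected$decay[[key]]), label = key)
  }
})

test_that("the study-shaped template has the right shape and determinism", {
  st <- study_template(seed = 9L)
  expect_equal(st$matrix$n_taxa, 16L)
  expect_equal(st$matrix$n_char, 110L)
  expect_identical(which(st$matrix$char_type == "ordered"), 21L)
  frac <- mean(st$matrix$tokens == "?")
  expect_gt(frac, 0.12); expect_lt(frac, 0.28)
  st2 <- study_template(seed = 9L)
  expect_identical(st$matrix$tokens, st2$matrix$tokens)
  expect_identical(split_signature(st$truth), split_signature(st2$truth))
})

test_that("a low-homoplasy study-scale simulation recovers its truth", {
  set.seed(422)
  tree <- random_topology(sample(sprintf("t%02d", 1:16)))
  ep <- edge_change_probs(tree, internal = 0.05, pendant = 0.02)
  sim <- simulate_matrix(tree, n_char = 110L, edge_prob = ep,
                         state_counts = 4L, redraw_constant = TRUE,
                         seed = 423L)
  r <- exact_search(sim$matrix)
  expect_length(r$trees, 1L)
  expect_identical(split_signature(r$trees[[1L]]),
                   split_signature(sim$truth))
})
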
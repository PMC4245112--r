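test_that("decay index of a single supported split is 1", {
  # one informative character: lengths over the 3 quartet topologies are
  # 1, 2, 2, so the best tree lacking {A,B} is one step longer
  m <- character_matrix(matrix(c("0", "0", "1", "1"), 4L, 1L),
                        taxa = LETTERS[1:4])
  lens <- vapply(enumerate_topologies(LETTERS[1:4]), function(tr) {
    tree_length(tr, m)$total_length
  }, numeric(1L))
  expect_setequal(lens, c(1, 2, 2))
  best <- exact_search(m)
  expect_equal(bremer_support(m, c("A", "B"), best = best), 1L)
  expect_equal(bremer_support(m, c("A", "B"), best = best, method = "sweep"),
               1L)
})

test_that("decay by converse constraint equals decay by slack sweep", {
  set.seed(415)
  checked <- 0L
  for (i in 1:10) {
    m <- random_char_matrix(6L, 10L, miss = 0.05)
    best <- exact_search(m)
    cons <- strict_consensus(best$trees)
    taxa <- sort(m$taxa)
    for (mk in cladesearch:::split_masks(cons, taxa)) {
      grp <- taxa[cladesearch:::mask_to_idx_wide(mk, 6L)]
      d1 <- bremer_support(m, grp, best = best, method = "constraint")
      d2 <- bremer_support(m, grp, best = best, method = "sweep")
      expect_identical(d1, d2)
      expect_gte(d1, 1L)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 5L)
})

test_that("decay is undefined for groups outside the consensus", {
  fx <- fixture_small()
  best <- exact_search(fx$matrix)
  expect_warning(d <- bremer_support(fx$matrix, c("a", "c"), best = best),
                 "undefined")
  expect_true(is.na(d))
})

test_that("fixture decay indices match the enumeration-verified card", {
  fx <- fixture_small()
  best <- exact_search(fx$matrix)
  for (key in names(fx$expected$decay)) {
    grp <- strsplit(key, "+", fixed = TRUE)[[1L]]
    expect_equal(bremer_support(fx$matrix, grp, best = best),
                 fx$expected$decay[[key]], label = key)
  }
})

test_that("GC frequencies follow the definition on constructed counts", {
  # 6 taxa a..f; replicate outcomes constructed by hand:
  #   {c,d} in 60 of 100, {d,e} (contradicts {c,d}) in 25,
  #   {a,b} (compatible with both) in 90
  taxa <- letters[1:6]
  mk <- function(g) sum(2^(match(g, taxa) - 1L))
  masks <- c(mk(c("c", "d")), mk(c("d", "e")), mk(c("a", "b")))
  tab <- gc_group_frequencies(masks, c(60L, 25L, 90L), 100L, 6L, taxa)
  expect_equal(tab$f_abs[tab$group == "c+d"], 60)
  expect_equal(tab$f_gc[tab$group == "c+d"], 60 - 25)
  expect_equal(tab$f_gc[tab$group == "d+e"], 25 - 60)  # negative GC
  expect_equal(tab$f_gc[tab$group == "a+b"], 90)       # nothing contradicts
  # brute-force equivalence on random constructed replicate sets
  set.seed(416)
  for (i in 1:10) {
    n <- 6L
    cand <- unique(replicate(6L, {
      g <- sort(sample(taxa, sample(2:4, 1L)))
      mkx <- sum(2^(match(g, taxa) - 1L))
      if (bitwAnd(mkx, 1L) > 0L) mkx <- (2^n - 1) - mkx
      mkx
    }))
    counts <- sample(5:95, length(cand), replace = TRUE)
    tab <- gc_group_frequencies(cand, counts, 100L, n, taxa)
    for (r in seq_len(nrow(tab))) {
      contra <- vapply(seq_along(cand), function(j) {
        !cladesearch:::splits_compatible(cand[j], tab$mask[r], n)
      }, logical(1L))
      want <- tab$f_abs[r] -
        if (any(contra)) max(counts[contra]) else 0
      expect_equal(tab$f_gc[r], want)
    }
  }
})

test_that("bootstrap of an unambiguous matrix gives 100% support", {
  # every character supports the same split: no pseudoreplicate can disagree
  tok <- matrix(rep(c("0", "0", "0", "1", "1", "1"), 8L), 6L, 8L)
  m <- character_matrix(tok, taxa = letters[1:6])
  bt <- bootstrap(m, n_pseudoreplicates = 60L, seed = 5L,
                  n_addition_sequences = 3L)
  split_row <- bt[bt$group == "d+e+f", ]
  expect_equal(split_row$f_abs, 100)
  expect_equal(split_row$f_gc, 100)
})

test_that("bootstrap is deterministic given the seed", {
  fx <- fixture_small()
  b1 <- bootstrap(fx$matrix, n_pseudoreplicates = 40L, seed = 7L,
                  n_addition_sequences = 3L)
  b2 <- bootstrap(fx$matrix, n_pseudoreplicates = 40L, seed = 7L,
                  n_addition_sequences = 3L)
  expect_identical(b1, b2)
  expect_error(bootstrap(fx$matrix, 40L), "seed")
})

test_that("replicate-to-replicate spread shrinks with more replicates", {
  # binomial sampling error ~ sqrt(p(1-p)/B): quadrupling B should about
  # halve the spread of f_abs across independent runs (loose tolerance)
  fx <- fixture_small()
  f_at <- function(B, seeds) {
    vapply(seeds, function(s) {
      bt <- bootstrap(fx$matrix, n_pseudoreplicates = B, seed = s,
                      n_addition_sequences = 2L)
      hit <- bt$f_abs[bt$group == "c+d+e+f"]
      if (length(hit)) hit else 0
    }, numeric(1L))
  }
  sd_small <- sd(f_at(50L, 1:10))
  sd_large <- sd(f_at(200L, 1:10))
  expect_lt(sd_large, sd_small)
})

test_that("the support report joins decay and bootstrap per consensus clade", {
  fx <- fixture_small()
  best <- exact_search(fx$matrix)
  bt <- bootstrap(fx$matrix, n_pseudoreplicates = 80L, seed = 11L,
                  n_addition_sequences = 3L)
  rep <- support_report(fx$matrix, best, bt)
  expect_setequal(rep$table$group, names(fx$expected$decay))
  expect_identical(setNames(rep$table$decay, rep$table$group)[
    names(fx$expected$decay)], fx$expected$decay)
  expect_true(all(rep$table$f_gc <= rep$table$f_abs))
  expect_true(all(rep$table$f_abs >= -100 & rep$table$f_abs <= 100))
  # annotated newick carries decay/abs/gc labels
  expect_match(rep$newick, "\\)[0-9]+/[0-9]+/")
})
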
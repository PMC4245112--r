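#' Monophyly constraints for tree searches
#'
#' `require_monophyly(group)` restricts a search to trees in which the
#' group forms a clade (one side of a bipartition); `forbid_monophyly`
#' to trees in which it does not. A "sister taxa X and Y" hypothesis is
#' `require_monophyly(c("X", "Y"))`.
#'
#' @param group character vector of at least 2 taxon labels, a proper
#'   subset of the matrix taxa.
#' @return a `constraint` object.
#' @export
require_monophyly <- function(group) new_constraint("require", group)

#' @rdname require_monophyly
#' @export
forbid_monophyly <- function(group) new_constraint("forbid", group)

new_constraint <- function(mode, group) {
  group <- unique(as.character(group))
  if (length(group) < 2L) stop("a constraint group needs at least 2 taxa")
  structure(list(mode = mode, group = sort(group)), class = "constraint")
}

# validate constraints against a matrix; returns list(req=, forb=) of masks
constraint_masks <- function(m, constraints) {
  if (inherits(constraints, "constraint")) constraints <- list(constraints)
  req <- integer(0L); forb <- integer(0L)
  seen <- list(require = character(0L), forbid = character(0L))
  for (ct in constraints) {
    stopifnot(inherits(ct, "constraint"))
    if (length(ct$group) >= m$n_taxa) {
      stop("constraint group must be a proper subset of the taxa")
    }
    key <- paste(ct$group, collapse = "\r")
    other <- if (ct$mode == "require") "forbid" else "require"
    if (key %in% seen[[other]]) {
      stop("contradictory constraints on group: ",
           paste(ct$group, collapse = ", "))
    }
    seen[[ct$mode]] <- c(seen[[ct$mode]], key)
    mk <- group_mask(m, ct$group)
    if (ct$mode == "require") req <- c(req, mk) else forb <- c(forb, mk)
  }
  list(req = req, forb = forb)
}

# deterministic farthest-first taxon addition order: placing the most
# mutually conflicting rows first makes partial lengths grow early, which
# tightens branch-and-bound pruning; members of require-monophyly groups are
# placed first so the partial monophyly check binds from the top of the
# search tree; the search RESULT is order-independent
addition_order <- function(m, req_members = character(0L)) {
  n <- m$n_taxa
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(m$weights *
        (bitwAnd(m$masks[i, ], m$masks[j, ]) == 0L))
    }
  }
  pick <- which(d == max(d), arr.ind = TRUE)[1L, ]
  ord <- as.integer(sort(pick))
  while (length(ord) < n) {
    rest <- setdiff(seq_len(n), ord)
    gain <- vapply(rest, function(t) sum(d[t, ord]), numeric(1L))
    ord <- c(ord, rest[which.max(gain)])
  }
  if (length(req_members)) {
    grp <- which(m$taxa %in% req_members)
    ord <- c(ord[ord %in% grp], ord[!(ord %in% grp)])
  }
  ord
}

# reorder matrix rows (used to present taxa to the C++ search kernels)
permute_rows <- function(m, ord) {
  m$taxa <- m$taxa[ord]
  m$tokens <- m$tokens[ord, , drop = FALSE]
  m$masks <- m$masks[ord, , drop = FALSE]
  m
}

# characters with g == m add the same number of steps to every binary tree;
# strip them from the kernels and add their constant contribution back
informative_split <- function(m, weights = m$weights) {
  mm <- integer(m$n_char); gg <- integer(m$n_char)
  for (c in seq_len(m$n_char)) {
    mm[c] <- min_steps_masks(m$masks[, c], m$char_type[c])
    gg[c] <- max_steps_star_masks(m$masks[, c], m$char_type[c])
  }
  w_eff <- as.integer(weights)
  drop <- gg == mm
  w_eff[drop] <- 0L
  list(weights = w_eff, m = mm,
       base = sum(as.numeric(weights[drop]) * mm[drop]))
}

# greedy disjoint matching of provably incompatible character pairs: two
# binary characters whose determinate cells show all four state combinations
# cannot both be homoplasy-free on one tree, adding >= 1 joint step
incompatible_pairs <- function(m, w_eff) {
  cand <- which(w_eff > 0L & m$char_type == "unordered" &
                  apply(m$masks, 2L, function(col) {
                    length(unique(col[mask_popcount_vec(col) == 1L])) == 2L
                  }))
  used <- logical(m$n_char)
  pairs <- matrix(0L, 0L, 2L)
  for (i in cand) {
    if (used[i]) next
    for (j in cand[cand > i]) {
      if (used[j]) next
      det <- mask_popcount_vec(m$masks[, i]) == 1L &
             mask_popcount_vec(m$masks[, j]) == 1L
      if (sum(det) < 4L) next
      combos <- unique(paste(m$masks[det, i], m$masks[det, j]))
      if (length(combos) == 4L) {
        pairs <- rbind(pairs, c(i - 1L, j - 1L))
        used[i] <- used[j] <- TRUE
        break
      }
    }
  }
  pairs
}

mask_popcount_vec <- function(v) {
  vapply(v, mask_popcount, integer(1L))
}

# run expr under a fixed RNG state, restoring the caller's state afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# shared post-processing: raw C++ edge arrays -> collapsed, deduplicated phylos
finish_search <- function(m, raw, algorithm, seed, collapse) {
  if (length(raw$eu) == 0L || raw$best_length < 0) {
    stop("search returned no tree satisfying the constraints")
  }
  if (isTRUE(raw$truncated)) {
    warning("tree buffer filled; the returned tree set may be incomplete")
  }
  trees <- mapply(function(eu, ev) edges_to_phylo(eu, ev, m$taxa),
                  raw$eu, raw$ev, SIMPLIFY = FALSE)
  lens <- raw$lengths
  if (collapse) {
    trees <- lapply(trees, collapse_rule1, matrix = m)
  }
  sig <- vapply(trees, function(tr) {
    paste(split_masks(tr, sort(m$taxa)), collapse = "/")
  }, character(1L))
  first <- !duplicated(sig)
  structure(list(best_length = raw$best_length,
                 trees = trees[first],
                 tree_lengths = lens[first],
                 algorithm = algorithm,
                 seed = seed,
                 nodes_visited = raw$nodes_visited,
                 truncated = isTRUE(raw$truncated)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("%s parsimony search: best length %d, %d tree(s) retained\n",
              x$algorithm, as.integer(x$best_length), length(x$trees)))
  invisible(x)
}

#' Exact maximum-parsimony search (branch and bound)
#'
#' Finds all binary trees within `slack` steps of the optimum by implicit
#' enumeration: taxa are added one at a time (in a deterministic
#' farthest-first order chosen purely for speed), and any partial tree
#' whose length plus an admissible lower bound on the remaining additions
#' exceeds the current incumbent is pruned. The incumbent is initialized
#' from a fast heuristic pass; since pruning is strict, the returned set is
#' provably complete and independent of the addition order. Found trees are
#' rule-1 collapsed (see [collapse_rule1()]) and deduplicated by
#' bipartition-set equality, in that order.
#'
#' @param matrix a [character_matrix()] with 4 to 20 taxa.
#' @param constraints list of [require_monophyly()] / [forbid_monophyly()]
#'   constraints (default none).
#' @param slack retain all trees within this many steps of the optimum.
#' @param collapse collapse zero-minimum-length branches before
#'   deduplication (default TRUE; set FALSE to keep the raw binary trees).
#' @param max_trees buffer guard on the number of retained trees.
#' @return a `search_result`: `best_length`, `trees`, `tree_lengths`,
#'   `algorithm`, `seed`, `nodes_visited`.
#' @export
exact_search <- function(matrix, constraints = list(), slack = 0L,
                         collapse = TRUE, max_trees = 100000L) {
  stopifnot(inherits(matrix, "char_matrix"))
  if (matrix$n_taxa < 4L) stop("search needs at least 4 taxa")
  if (matrix$n_taxa > 20L) {
    stop("exact search is guarded to 20 taxa; use heuristic_search()")
  }
  if (inherits(constraints, "constraint")) constraints <- list(constraints)
  req_members <- unlist(lapply(constraints, function(ct) {
    if (ct$mode == "require") ct$group else character(0L)
  }))
  pm <- permute_rows(matrix, addition_order(matrix, req_members))
  cm <- constraint_masks(pm, constraints)
  info <- informative_split(pm)
  # a quick heuristic pass supplies a valid upper bound for pruning; the
  # caller's RNG state is untouched and the result stays exact
  upper <- with_local_seed(20230201L, tryCatch({
    h <- cpp_heuristic_search(pm$masks, pm$char_type == "ordered",
                              info$weights, 2L, 0L, cm$req, cm$forb, 1L)
    h$best_length
  }, error = function(e) -1))
  raw <- cpp_exact_search(pm$masks, pm$char_type == "ordered",
                          info$weights, as.integer(slack), info$m,
                          incompatible_pairs(pm, info$weights),
                          cm$req, cm$forb, as.integer(max_trees),
                          as.numeric(upper))
  raw$best_length <- raw$best_length + info$base
  raw$lengths <- raw$lengths + info$base
  finish_search(pm, raw, "exact", NA_integer_, collapse)
}

#' Heuristic maximum-parsimony search (random addition + TBR)
#'
#' Builds trees by stepwise addition under random taxon orders and refines
#' each by tree-bisection-reconnection branch swapping (whose neighborhood
#' contains all subtree-pruning-regrafting moves), then expands the set of
#' retained trees by sweeping the TBR neighborhood of every tree within
#' `slack` steps of the best found. Deterministic given `seed`. Not
#' guaranteed optimal; see [exact_search()] for a provably complete search.
#'
#' @inheritParams exact_search
#' @param n_addition_sequences number of random addition orders.
#' @param seed integer RNG seed (mandatory: there is no global-state mode).
#' @param pool_cap maximum number of distinct trees retained.
#' @return a `search_result`.
#' @export
heuristic_search <- function(matrix, n_addition_sequences = 10L, seed,
                             constraints = list(), slack = 0L,
                             collapse = TRUE, pool_cap = 500L) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("heuristic_search requires an explicit seed")
  }
  set.seed(as.integer(seed))
  res <- heuristic_core(matrix, n_addition_sequences, constraints, slack,
                        pool_cap)
  finish_search(matrix, res, "heuristic", as.integer(seed), collapse)
}

# seedless core so that bootstrap() can drive many searches off one RNG stream
heuristic_core <- function(matrix, n_addition_sequences, constraints, slack,
                           pool_cap, weights = matrix$weights) {
  stopifnot(inherits(matrix, "char_matrix"))
  if (matrix$n_taxa < 4L) stop("search needs at least 4 taxa")
  cm <- constraint_masks(matrix, constraints)
  info <- informative_split(matrix, weights)
  raw <- cpp_heuristic_search(matrix$masks, matrix$char_type == "ordered",
                              info$weights,
                              as.integer(n_addition_sequences),
                              as.integer(slack), cm$req, cm$forb,
                              as.integer(pool_cap))
  if (raw$best_length >= 0) raw$best_length <- raw$best_length + info$base
  raw$lengths <- raw$lengths + info$base
  raw
}

#' Cost of forcing a group to be monophyletic
#'
#' Reruns the exact search constrained to trees where `group` is a clade
#' and reports the constrained optimum and its excess over the
#' unconstrained optimum; the standard test of how many extra steps an
#' alternative sister-group hypothesis costs.
#'
#' @param matrix a [character_matrix()].
#' @param group taxon labels to force together.
#' @param best optional precomputed unconstrained `search_result`.
#' @return list with `constrained_length` and `delta`.
#' @export
constrained_extra_steps <- function(matrix, group, best = NULL) {
  if (is.null(best)) best <- exact_search(matrix)
  con <- exact_search(matrix, constraints = list(require_monophyly(group)))
  list(constrained_length = con$best_length,
       delta = con$best_length - best$best_length)
}
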
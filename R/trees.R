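#' Parse and write newick trees
#'
#' Thin wrappers around ape's newick reader/writer. Branch lengths, if
#' present, are ignored throughout the package: parsimony deals in
#' topologies only. Trees are handled unrooted; parsimony length is
#' invariant to the rooting, and consensus/support bookkeeping operates on
#' bipartitions (splits), which are rooting-free.
#'
#' @param text newick string.
#' @return `parse_newick` returns an ape `phylo`; `write_newick` a string.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed newick: ", substr(text, 1L, 60L))
  }
  tr$edge.length <- NULL
  tr$node.label <- NULL
  tr
}

#' @rdname parse_newick
#' @param tree an ape `phylo` object.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$edge.length <- NULL
  ape::write.tree(tree)
}

# list of tip-index vectors under every node (tips 1..n, internals n+1..)
node_tipsets <- function(tree) {
  nt <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- i
  for (r in seq_len(nrow(po))) {
    below[[po[r, 1L]]] <- c(below[[po[r, 1L]]], below[[po[r, 2L]]])
  }
  below
}

# nontrivial splits of a tree as canonical bitmasks over `taxa` order
# (the side NOT containing taxa[1] is stored)
split_masks <- function(tree, taxa = sort(tree$tip.label)) {
  n <- length(taxa)
  if (length(tree$tip.label) != n || anyNA(match(tree$tip.label, taxa))) {
    stop("tree leaf set does not match the given taxon set")
  }
  tipbit <- 2^(match(tree$tip.label, taxa) - 1L)
  below <- node_tipsets(tree)
  nt <- length(tree$tip.label)
  masks <- vapply(below[(nt + 1L):(nt + tree$Nnode)],
                  function(tips) sum(tipbit[tips]), numeric(1L))
  full <- 2^n - 1
  has_ref <- bitwAnd(masks, 1L) > 0
  masks[has_ref] <- full - masks[has_ref]
  sz <- vapply(masks, function(mk) mask_popcount_wide(mk, n), integer(1L))
  sort(unique(masks[sz >= 2 & sz <= n - 2]))
}

mask_popcount_wide <- function(mask, n) {
  sum(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' One bipartition per internal edge; a binary n-leaf tree has n - 3.
#' Each is reported as the group of taxon labels on the side not containing
#' the reference taxon (the alphabetically first label).
#'
#' @param tree an ape `phylo` with >= 4 leaves.
#' @return list of character vectors (sorted taxon labels).
#' @examples
#' bipartitions(parse_newick("((A,B),(C,D));"))
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 4L) stop("need at least 4 leaves")
  taxa <- sort(tree$tip.label)
  lapply(split_masks(tree, taxa), function(mk) {
    taxa[mask_to_idx_wide(mk, length(taxa))]
  })
}

mask_to_idx_wide <- function(mask, n) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
}

# are two canonical split masks compatible on n taxa?
splits_compatible <- function(a, b, n) {
  full <- 2^n - 1
  bitwAnd(a, b) == 0 || bitwAnd(a, full - b) == 0 ||
    bitwAnd(full - a, b) == 0 || bitwAnd(full - a, full - b) == 0
}

# build a (possibly polytomous) phylo from compatible canonical split masks
tree_from_splits <- function(masks, taxa) {
  n <- length(taxa)
  masks <- sort(unique(masks), decreasing = TRUE)
  sizes <- vapply(masks, function(mk) mask_popcount_wide(mk, n), integer(1L))
  masks <- masks[order(-sizes)]
  build <- function(members, avail) {
    # split masks nested inside `members`, take the maximal ones
    inside <- avail[vapply(avail, function(mk)
      all(mask_to_idx_wide(mk, n) %in% members), logical(1L))]
    maximal <- inside[!vapply(seq_along(inside), function(i) {
      any(vapply(inside, function(o)
        o != inside[i] &&
          all(mask_to_idx_wide(inside[i], n) %in% mask_to_idx_wide(o, n)),
        logical(1L)))
    }, logical(1L))]
    used <- integer(0L)
    parts <- character(0L)
    for (mk in maximal) {
      mem <- mask_to_idx_wide(mk, n)
      parts <- c(parts, build(mem, setdiff(inside, mk)))
      used <- c(used, mem)
    }
    singles <- setdiff(members, used)
    parts <- c(parts, taxa[singles])
    if (length(parts) == 1L) parts else
      paste0("(", paste(parts, collapse = ","), ")")
  }
  nw <- paste0(build(seq_len(n), masks), ";")
  ape::read.tree(text = nw)
}

#' Strict consensus of trees on a common leaf set
#'
#' Returns the tree whose bipartitions are exactly those present in every
#' input tree; conflicting regions collapse to polytomies.
#'
#' @param trees a list of `phylo` objects (or a `multiPhylo`).
#' @return a `phylo`, possibly polytomous.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1L)
  taxa <- sort(trees[[1L]]$tip.label)
  for (tr in trees) {
    if (!setequal(tr$tip.label, taxa)) {
      stop("trees have mismatched leaf sets")
    }
  }
  shared <- Reduce(intersect, lapply(trees, split_masks, taxa = taxa))
  tree_from_splits(shared, taxa)
}

#' Enumerate all unrooted binary topologies
#'
#' Generates every unrooted binary tree on the given labels exactly once by
#' sequential leaf insertion; there are (2n-5)!! of them. Intended as the
#' exhaustive oracle for small searches; guarded to 4 <= n <= 9.
#'
#' @param labels character vector of 4 to 9 leaf labels.
#' @return list of `phylo` objects.
#' @export
enumerate_topologies <- function(labels) {
  n <- length(labels)
  if (n < 4L || n > 9L) stop("enumerate_topologies supports 4 to 9 leaves")
  out <- vector("list", prod(seq(2L * n - 5L, 1L, by = -2L)))
  cnt <- 0L
  eu <- integer(2L * n - 3L); ev <- integer(2L * n - 3L)
  eu[1:3] <- n; ev[1:3] <- 0:2                       # 0-based, internal = n
  recurse <- function(k, m, nextInt) {
    if (k == n) {
      cnt <<- cnt + 1L
      out[[cnt]] <<- edges_to_phylo(eu[1:m], ev[1:m], labels)
      return(invisible())
    }
    for (e in seq_len(m)) {
      a <- eu[e]; b <- ev[e]
      ev[e] <<- nextInt
      eu[m + 1L] <<- nextInt; ev[m + 1L] <<- b
      eu[m + 2L] <<- nextInt; ev[m + 2L] <<- k
      recurse(k + 1L, m + 2L, nextInt + 1L)
      ev[e] <<- b
    }
  }
  recurse(3L, 3L, n + 1L)
  out
}

# undirected 0-based edge arrays (leaves 0..n-1) -> ape phylo
edges_to_phylo <- function(eu, ev, labels) {
  n <- length(labels)
  m <- length(eu)
  adj <- vector("list", 2L * n)
  for (i in seq_len(m)) {
    a <- eu[i] + 1L; b <- ev[i] + 1L
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  # BFS from an internal node adjacent to leaf 1, renumbering internals
  root <- adj[[1L]][1L]
  newid <- integer(2L * n)
  newid[seq_len(n)] <- seq_len(n)
  nxt <- n + 1L
  edge <- matrix(0L, m, 2L)
  r <- 0L
  queue <- list(c(root, 0L))
  newid[root] <- nxt; nxt <- nxt + 1L
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    u <- cur[1L]; parent <- cur[2L]
    for (v in adj[[u]]) {
      if (v == parent) next
      if (v > n && newid[v] == 0L) { newid[v] <- nxt; nxt <- nxt + 1L }
      r <- r + 1L
      edge[r, ] <- c(newid[u], newid[v])
      if (v > n) queue[[length(queue) + 1L]] <- c(v, u)
    }
  }
  structure(list(edge = edge, tip.label = labels, Nnode = nxt - n - 1L),
            class = "phylo")
}

#' Collapse zero-minimum-length branches (rule 1)
#'
#' Contracts internal branches whose minimum length over all
#' most-parsimonious reconstructions is zero, the "rule 1" collapsing
#' convention for reporting cladograms. A branch has minimum length zero
#' exactly when contracting it leaves the tree length unchanged, which is
#' how the test is implemented. Because individually ambiguous branches can
#' interact (two branches may each admit a zero-length reconstruction but
#' not in the same one), contraction proceeds iteratively - contract,
#' rescore, repeat to a fixpoint - which guarantees the collapsed tree has
#' the same length and no remaining zero-minimum branch.
#'
#' @param tree a `phylo` scored against `matrix` (leaves must match taxa).
#' @param matrix a [character_matrix()].
#' @return a `phylo`, possibly polytomous; same parsimony length.
#' @export
collapse_rule1 <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "char_matrix"))
  # work unrooted: a rooted tree's two root edges are one unrooted branch
  tree$edge.length <- NULL
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  masks <- matrix$masks[match(tree$tip.label, matrix$taxa), , drop = FALSE]
  ordered <- matrix$char_type == "ordered"
  w <- as.numeric(matrix$weights)
  nt <- length(tree$tip.label)
  score_edges <- function(edge) {
    sum(w * cpp_score_tree_general(edge, nt, masks, ordered))
  }
  L <- score_edges(tree$edge)
  repeat {
    internal <- which(tree$edge[, 2L] > nt)
    if (!length(internal)) break
    zero_min <- internal[vapply(internal, function(e) {
      edge2 <- tree$edge
      child <- edge2[e, 2L]
      edge2[edge2 == child] <- edge2[e, 1L]
      score_edges(edge2[-e, , drop = FALSE]) == L
    }, logical(1L))]
    if (!length(zero_min)) break
    contract <- function(rows) {
      tree$edge.length <- rep(1, nrow(tree$edge))
      tree$edge.length[rows] <- 0
      out <- ape::di2multi(tree, tol = 0.5)
      out$edge.length <- NULL
      out
    }
    all_at_once <- contract(zero_min)
    if (score_edges(all_at_once$edge) == L) {
      tree <- all_at_once
      if (length(zero_min) == length(internal)) break
      next  # re-test remaining branches on the collapsed tree
    }
    tree <- contract(zero_min[1L])  # interacting branches: one at a time
  }
  # the masks row order is tied to tip.label, which di2multi preserves
  tree$edge.length <- NULL
  tree
}
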
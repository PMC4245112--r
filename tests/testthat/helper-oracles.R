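# Independent brute-force oracles used throughout the suite. These never call
# the package's scoring kernels: lengths are computed by exhaustive
# enumeration of internal-node state assignments straight from the edge
# matrix, so they can arbitrate the C++ implementations.

# exhaustive minimum steps of one character column on a (small) phylo
brute_force_char_length <- function(tree, tokens, type = "unordered") {
  stopifnot(length(tokens) == length(tree$tip.label))
  if (!is.null(names(tokens))) tokens <- tokens[tree$tip.label]
  # leaf state sets, with ?/- normalized to the observed set
  cell_sets <- lapply(tokens, function(tk) {
    if (tk %in% c("?", "-")) NULL else as.integer(strsplit(tk, "")[[1L]])
  })
  observed <- sort(unique(unlist(cell_sets)))
  if (!length(observed)) observed <- 0L
  cell_sets[vapply(cell_sets, is.null, logical(1L))] <- list(observed)
  states <- if (type == "ordered") seq(min(observed), max(observed)) else observed
  nt <- length(tree$tip.label)
  n_int <- tree$Nnode
  grid <- do.call(expand.grid, rep(list(states), n_int))
  cost <- function(a, b) if (type == "ordered") abs(a - b) else as.integer(a != b)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    internal <- as.integer(grid[g, ])
    # leaves resolved best-case against the adjacent internal node
    total <- 0
    for (r in seq_len(nrow(tree$edge))) {
      p <- tree$edge[r, 1L]; ch <- tree$edge[r, 2L]
      sp <- internal[p - nt]
      total <- total +
        if (ch <= nt) min(vapply(cell_sets[[ch]], cost, numeric(1L), a = sp))
        else cost(sp, internal[ch - nt])
    }
    best <- min(best, total)
  }
  as.integer(best)
}

# random token matrix with missing and polymorphic cells
random_tokens <- function(n, nc, n_states = 3L, miss = 0.15, poly = 0.05) {
  tok <- matrix(as.character(sample(0:(n_states - 1L), n * nc, TRUE)), n, nc)
  flip <- matrix(runif(n * nc), n, nc)
  tok[flip < miss] <- sample(c("?", "-"), sum(flip < miss), TRUE)
  is_poly <- flip >= miss & flip < miss + poly
  if (any(is_poly)) {
    tok[is_poly] <- vapply(seq_len(sum(is_poly)), function(i) {
      paste(sort(sample(0:(n_states - 1L), 2L)), collapse = "")
    }, character(1L))
  }
  tok
}

random_char_matrix <- function(n, nc, n_states = 3L, miss = 0.15, poly = 0.05,
                               ordered_frac = 0.15) {
  ct <- ifelse(runif(nc) < ordered_frac, "ordered", "unordered")
  character_matrix(random_tokens(n, nc, n_states, miss, poly),
                   taxa = letters[seq_len(n)], char_type = ct)
}

# canonical split-set signature of a tree (for equality up to rotation)
split_signature <- function(tree, taxa = sort(tree$tip.label)) {
  paste(cladesearch:::split_masks(tree, taxa), collapse = "/")
}
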
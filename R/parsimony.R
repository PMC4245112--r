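#' Parsimony length of a tree
#'
#' Computes the minimum number of state changes (steps) the matrix requires
#' on the given topology. Unordered characters are optimized under Fitch
#' counting (any change costs 1); ordered (additive) characters under
#' linear state-distance costs. Both are solved exactly by dynamic
#' programming over states, which also handles polytomous trees directly.
#' Cells with several allowed states (polymorphisms, normalized missing
#' entries) are resolved best-case, the standard convention.
#'
#' @param tree `phylo`; leaf labels must equal the matrix taxa.
#' @param matrix a [character_matrix()].
#' @return object of class `parsimony_score`: `total_length` (weighted sum)
#'   and `per_char` (unweighted steps per character).
#' @export
tree_length <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "char_matrix"))
  if (!setequal(tree$tip.label, matrix$taxa) ||
      length(tree$tip.label) != matrix$n_taxa) {
    stop("tree leaves do not match matrix taxa")
  }
  masks <- matrix$masks[match(tree$tip.label, matrix$taxa), , drop = FALSE]
  s <- cpp_score_tree_general(tree$edge, length(tree$tip.label), masks,
                              matrix$char_type == "ordered")
  structure(list(total_length = sum(as.numeric(matrix$weights) * s),
                 per_char = as.integer(s)),
            class = "parsimony_score")
}

#' @export
print.parsimony_score <- function(x, ...) {
  cat("Tree length:", x$total_length, "steps over", length(x$per_char),
      "characters\n")
  invisible(x)
}

# column -> list of state masks; accepts tokens (character) or a 1-col matrix
column_masks <- function(column, taxa = NULL) {
  tokens <- matrix(as.character(column), ncol = 1L)
  m <- character_matrix(tokens,
                        taxa = taxa %||% paste0("t", seq_along(column)))
  m$masks[, 1L]
}

#' Single-character lengths
#'
#' `char_length_unordered` scores one column under Fitch (unordered)
#' optimization, `char_length_ordered` under additive costs. `column` is a
#' vector of state tokens (`"0"`, `"?"`, `"02"`, ...) named by taxon or
#' given in `tree$tip.label` order.
#'
#' @param tree a `phylo`.
#' @param column character vector of state tokens, one per leaf.
#' @return integer number of steps.
#' @export
char_length_unordered <- function(tree, column) {
  char_length_one(tree, column, "unordered")
}

#' @rdname char_length_unordered
#' @export
char_length_ordered <- function(tree, column) {
  char_length_one(tree, column, "ordered")
}

char_length_one <- function(tree, column, type) {
  taxa <- names(column) %||% tree$tip.label
  m <- character_matrix(matrix(as.character(column), ncol = 1L),
                        taxa = taxa, char_type = type)
  tree_length(tree, m)$per_char[1L]
}

#' Per-character step bounds
#'
#' `min_steps` is the smallest number of steps any tree can require for the
#' column (for unordered characters, the minimum number of states needed to
#' cover every cell minus one, a minimum hitting set over the state sets;
#' for ordered characters, the smallest achievable state range).
#' `max_steps_star` is the column length on the completely unresolved star
#' tree, the worst relevant case used by the retention index.
#'
#' @param column character vector of state tokens.
#' @param char_type `"unordered"` or `"ordered"`.
#' @return integer.
#' @export
min_steps <- function(column, char_type = c("unordered", "ordered")) {
  char_type <- match.arg(char_type)
  cells <- column_masks(column)
  min_steps_masks(cells, char_type)
}

min_steps_masks <- function(cells, char_type) {
  if (char_type == "unordered") {
    min_hitting_set(cells) - 1L
  } else {
    lo <- max(vapply(cells, function(mk) min(mask_to_states(mk)), numeric(1L)))
    hi <- min(vapply(cells, function(mk) max(mask_to_states(mk)), numeric(1L)))
    as.integer(max(0, lo - hi))
  }
}

# smallest number of states hitting every cell set (brute force over the
# <= 2^10 subsets of observed states)
min_hitting_set <- function(cells) {
  obs <- Reduce(bitwOr, cells, 0L)
  if (obs == 0L) return(1L)
  states <- mask_to_states(obs)
  for (k in seq_along(states)) {
    combs <- combn(states, k)
    for (j in seq_len(ncol(combs))) {
      s <- states_to_mask(combs[, j])
      if (all(vapply(cells, function(mk) bitwAnd(mk, s) > 0L, logical(1L)))) {
        return(k)
      }
    }
  }
  length(states)
}

#' @rdname min_steps
#' @export
max_steps_star <- function(column, char_type = c("unordered", "ordered")) {
  char_type <- match.arg(char_type)
  cells <- column_masks(column)
  max_steps_star_masks(cells, char_type)
}

max_steps_star_masks <- function(cells, char_type) {
  n <- length(cells)
  if (char_type == "unordered") {
    best <- max(vapply(0:9, function(y) {
      sum(vapply(cells, function(mk) bitwAnd(mk, bitwShiftL(1L, y)) > 0L,
                 logical(1L)))
    }, integer(1L)))
    as.integer(n - best)
  } else {
    as.integer(min(vapply(0:9, function(y) {
      sum(vapply(cells, function(mk) min(abs(mask_to_states(mk) - y)),
                 numeric(1L)))
    }, numeric(1L))))
  }
}

#' Ensemble consistency and retention indices
#'
#' CI = sum(m_i) / sum(s_i) and RI = (sum(g_i) - sum(s_i)) /
#' (sum(g_i) - sum(m_i)), where m_i is the character's minimum conceivable
#' steps, s_i its observed steps on the scored tree and g_i its length on
#' the star tree; all sums are weighted. Both statistics are reported over
#' all characters and, as a secondary variant, over parsimony-informative
#' characters only (those with g_i > m_i, the ones able to show homoplasy).
#'
#' @param matrix a [character_matrix()].
#' @param score a `parsimony_score` from [tree_length()] on the same matrix.
#' @return object of class `fit_stats` with per-character `m`, `s`, `g` and
#'   ensemble `CI`, `RI`, `CI_informative`, `RI_informative`.
#' @export
fit_statistics <- function(matrix, score) {
  stopifnot(inherits(matrix, "char_matrix"),
            inherits(score, "parsimony_score"))
  s <- score$per_char
  if (length(s) != matrix$n_char) stop("score does not match matrix")
  m <- integer(matrix$n_char)
  g <- integer(matrix$n_char)
  for (c in seq_len(matrix$n_char)) {
    cells <- matrix$masks[, c]
    m[c] <- min_steps_masks(cells, matrix$char_type[c])
    g[c] <- max_steps_star_masks(cells, matrix$char_type[c])
  }
  w <- as.numeric(matrix$weights)
  ens <- function(keep) {
    sw <- sum(w[keep] * s[keep]); mw <- sum(w[keep] * m[keep])
    gw <- sum(w[keep] * g[keep])
    ci <- if (sw > 0) mw / sw else NA_real_
    ri <- if (gw > mw) (gw - sw) / (gw - mw) else NA_real_
    c(ci = ci, ri = ri)
  }
  all_v <- ens(rep(TRUE, matrix$n_char))
  inf_v <- ens(g > m)
  structure(list(m = m, s = s, g = g,
                 CI = unname(all_v["ci"]), RI = unname(all_v["ri"]),
                 CI_informative = unname(inf_v["ci"]),
                 RI_informative = unname(inf_v["ri"])),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("CI = %.4f, RI = %.4f (all characters)\n", x$CI, x$RI))
  cat(sprintf("CI = %.4f, RI = %.4f (informative only)\n",
              x$CI_informative, x$RI_informative))
  invisible(x)
}

#' Per-character diagnostics table
#'
#' @param matrix a [character_matrix()].
#' @param score a `parsimony_score` for a tree of interest.
#' @return data.frame with 1-based character index, type, weight, m, s, g
#'   and per-character ci and ri (NA where undefined).
#' @export
character_diagnostics <- function(matrix, score) {
  fs <- fit_statistics(matrix, score)
  data.frame(
    index = seq_len(matrix$n_char),
    type = matrix$char_type,
    weight = matrix$weights,
    m = fs$m, s = fs$s, g = fs$g,
    ci = ifelse(fs$s > 0, fs$m / fs$s, NA_real_),
    ri = ifelse(fs$g > fs$m, (fs$g - fs$s) / (fs$g - fs$m), NA_real_))
}
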
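#' Bremer decay index of a group
#'
#' The decay index d of a clade is the number of extra steps needed before
#' trees lacking the clade appear: d = (optimal length among trees in which
#' the group is NOT monophyletic) - (unconstrained optimum). Two equivalent
#' routes are provided: a converse-constraint exact search
#' (`method = "constraint"`, the default) and a sweep of increasingly
#' suboptimal unconstrained searches (`method = "sweep"`).
#'
#' @param matrix a [character_matrix()].
#' @param group taxon labels of the clade.
#' @param best optional precomputed unconstrained `search_result`.
#' @param method `"constraint"` or `"sweep"`.
#' @param max_sweep upper bound for the sweep method.
#' @return integer decay index, or NA if the group is not in the strict
#'   consensus of the optimal trees (support undefined), with a warning.
#' @export
bremer_support <- function(matrix, group, best = NULL,
                           method = c("constraint", "sweep"),
                           max_sweep = 50L) {
  method <- match.arg(method)
  if (is.null(best)) best <- exact_search(matrix)
  taxa <- sort(matrix$taxa)
  gmask <- sum(2^(match(sort(group), taxa) - 1L))
  full <- 2^matrix$n_taxa - 1
  if (bitwAnd(gmask, 1L) > 0L) gmask <- full - gmask
  cons_masks <- split_masks(strict_consensus(best$trees), taxa)
  if (!(gmask %in% cons_masks)) {
    warning("group is not in the strict consensus; decay index undefined")
    return(NA_integer_)
  }
  if (method == "constraint") {
    con <- exact_search(matrix,
                        constraints = list(forbid_monophyly(group)),
                        collapse = FALSE)
    return(as.integer(con$best_length - best$best_length))
  }
  for (k in seq_len(max_sweep)) {
    res <- exact_search(matrix, slack = k, collapse = FALSE)
    lacking <- vapply(res$trees, function(tr) {
      !(gmask %in% split_masks(tr, taxa))
    }, logical(1L))
    if (any(lacking)) {
      return(as.integer(min(res$tree_lengths[lacking]) - best$best_length))
    }
  }
  stop("decay index exceeds max_sweep = ", max_sweep)
}

#' Bootstrap resampling with absolute and GC group frequencies
#'
#' Each pseudoreplicate resamples the characters with replacement
#' (implemented as re-weighting by the resample counts), runs a heuristic
#' search, and is summarized by the strict consensus of the trees it
#' retains: a group is counted for the replicate only when it is present
#' unambiguously. The absolute frequency of a group is the percentage of
#' replicates whose summary contains it; its GC frequency is that
#' percentage minus the highest frequency among groups contradicting it
#' (pairwise incompatible bipartitions on the same taxa), so GC is negative
#' for groups beaten by a contradictory group.
#'
#' @param matrix a [character_matrix()].
#' @param n_pseudoreplicates number of bootstrap replicates (>= 100
#'   recommended for stable percentages).
#' @param seed integer RNG seed (mandatory).
#' @param n_addition_sequences random addition sequences per replicate.
#' @param pool_cap per-replicate cap on retained trees.
#' @return a `support_table` data.frame with one row per group observed in
#'   any replicate summary: `group` (label string), `f_abs`, `f_gc` (both
#'   percentages). Attributes: `taxa`, `n_replicates`, `counts`.
#' @export
bootstrap <- function(matrix, n_pseudoreplicates = 1000L, seed,
                      n_addition_sequences = 5L, pool_cap = 100L) {
  stopifnot(inherits(matrix, "char_matrix"))
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("bootstrap requires an explicit seed")
  }
  if (n_pseudoreplicates < 1L) stop("need at least one pseudoreplicate")
  set.seed(as.integer(seed))
  taxa <- sort(matrix$taxa)
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(n_pseudoreplicates)) {
    draw <- sample.int(matrix$n_char, matrix$n_char, replace = TRUE)
    w <- tabulate(draw, nbins = matrix$n_char) * matrix$weights
    raw <- heuristic_core(matrix, n_addition_sequences, list(), 0L,
                          pool_cap, weights = w)
    if (length(raw$eu) == 0L) next
    reps <- mapply(function(eu, ev) {
      split_masks(edges_to_phylo(eu, ev, matrix$taxa), taxa)
    }, raw$eu, raw$ev, SIMPLIFY = FALSE)
    shared <- Reduce(intersect, reps)
    for (mk in shared) {
      key <- as.character(mk)
      counts[[key]] <- get0(key, envir = counts, ifnotfound = 0L) + 1L
    }
  }
  masks <- as.numeric(ls(counts))
  tallies <- vapply(as.character(masks), function(k) counts[[k]],
                    integer(1L))
  gc_group_frequencies(masks, tallies, n_pseudoreplicates, matrix$n_taxa,
                       taxa)
}

#' GC frequencies from replicate group counts
#'
#' Turns a table of (group, count) replicate outcomes into absolute and GC
#' percentages. Exposed separately so the GC definition can be checked
#' directly against constructed replicate multisets.
#'
#' @param masks canonical split masks over `taxa` (sorted label order,
#'   side not containing the first taxon).
#' @param tallies replicate counts, parallel to `masks`.
#' @param B number of replicates.
#' @param n_taxa number of taxa.
#' @param taxa sorted taxon labels (for the group label column).
#' @return a `support_table` data.frame.
#' @export
gc_group_frequencies <- function(masks, tallies, B, n_taxa, taxa) {
  ord <- order(-tallies, masks)
  masks <- masks[ord]; tallies <- tallies[ord]
  f_abs <- 100 * tallies / B
  f_gc <- vapply(seq_along(masks), function(i) {
    contra <- !vapply(masks, splits_compatible, logical(1L),
                      b = masks[i], n = n_taxa)
    f_abs[i] - if (any(contra)) max(f_abs[contra]) else 0
  }, numeric(1L))
  lab <- vapply(masks, function(mk) {
    paste(taxa[mask_to_idx_wide(mk, n_taxa)], collapse = "+")
  }, character(1L))
  out <- data.frame(group = lab, mask = masks, f_abs = f_abs, f_gc = f_gc,
                    stringsAsFactors = FALSE)
  attr(out, "taxa") <- taxa
  attr(out, "n_replicates") <- B
  class(out) <- c("support_table", "data.frame")
  out
}

#' Joint support report: decay plus bootstrap frequencies per consensus clade
#'
#' For every nontrivial bipartition of the strict consensus of the optimal
#' trees, computes the Bremer decay index (converse-constraint search) and
#' looks up the bootstrap absolute and GC frequencies, and annotates the
#' consensus tree with "decay/abs/gc" internal node labels.
#'
#' @param matrix a [character_matrix()].
#' @param best a `search_result` from [exact_search()] or
#'   [heuristic_search()].
#' @param bootstrap_table a `support_table` from [bootstrap()] on the same
#'   matrix.
#' @return list: `table` (data.frame group/decay/f_abs/f_gc), `consensus`
#'   (annotated `phylo`), `newick` (its newick string).
#' @export
support_report <- function(matrix, best, bootstrap_table) {
  taxa <- sort(matrix$taxa)
  cons <- strict_consensus(best$trees)
  masks <- split_masks(cons, taxa)
  decay <- vapply(masks, function(mk) {
    grp <- taxa[mask_to_idx_wide(mk, matrix$n_taxa)]
    bremer_support(matrix, grp, best = best)
  }, integer(1L))
  bt <- bootstrap_table
  hit <- match(masks, bt$mask)
  f_abs <- ifelse(is.na(hit), 0, bt$f_abs[hit])
  f_gc <- numeric(length(masks))
  for (i in seq_along(masks)) {
    if (!is.na(hit[i])) {
      f_gc[i] <- bt$f_gc[hit[i]]
    } else {
      contra <- !vapply(bt$mask, splits_compatible, logical(1L),
                        b = masks[i], n = matrix$n_taxa)
      f_gc[i] <- 0 - if (any(contra)) max(bt$f_abs[contra]) else 0
    }
  }
  lab <- vapply(masks, function(mk) {
    paste(taxa[mask_to_idx_wide(mk, matrix$n_taxa)], collapse = "+")
  }, character(1L))
  tab <- data.frame(group = lab, mask = masks, decay = decay,
                    f_abs = f_abs, f_gc = f_gc, stringsAsFactors = FALSE)
  # annotate consensus internal nodes
  nt <- length(cons$tip.label)
  tipbit <- 2^(match(cons$tip.label, taxa) - 1L)
  below <- node_tipsets(cons)
  full <- 2^matrix$n_taxa - 1
  cons$node.label <- vapply(seq_len(cons$Nnode), function(i) {
    mk <- sum(tipbit[below[[nt + i]]])
    if (bitwAnd(mk, 1L) > 0L) mk <- full - mk
    j <- match(mk, masks)
    if (is.na(j)) "" else sprintf("%d/%.0f/%.0f", decay[j], f_abs[j], f_gc[j])
  }, character(1L))
  list(table = tab, consensus = cons, newick = ape::write.tree(cons))
}
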
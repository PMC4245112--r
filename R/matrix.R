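#' Discrete morphological character matrix
#'
#' Constructs a validated character matrix of taxa by characters. Each cell
#' is a token: a single digit `"0"`–`"9"`, a multi-digit string such as
#' `"01"` for a polymorphic observation, `"?"` for missing, or `"-"` for
#' inapplicable. Missing and inapplicable cells are both normalized, for
#' optimization purposes, to the full set of states observed elsewhere in
#' the same character (the standard equally-weighted treatment, under which
#' such cells can never add steps). Characters are either `"unordered"`
#' (any state change costs one step) or `"ordered"` (additive: a change
#' from state a to state b costs |a - b| steps).
#'
#' @param tokens character matrix (taxa in rows, characters in columns) of
#'   state tokens as described above.
#' @param taxa character vector of unique taxon labels, one per row.
#' @param char_type per-character type, `"unordered"` or `"ordered"`;
#'   recycled if length 1. Default all unordered.
#' @param weights per-character positive integer weights. Default 1.
#' @return An object of class `char_matrix` with fields `taxa`, `tokens`,
#'   `masks` (normalized state-set bitmasks), `char_type`, `weights`,
#'   `n_taxa`, `n_char`.
#' @examples
#' m <- character_matrix(rbind(A = c("0", "0"), B = c("0", "1"),
#'                             C = c("1", "?"), D = c("1", "1")),
#'                       taxa = c("A", "B", "C", "D"))
#' m$n_char
#' @export
character_matrix <- function(tokens, taxa = rownames(tokens),
                             char_type = "unordered", weights = 1L) {
  tokens <- as.matrix(tokens)
  storage.mode(tokens) <- "character"
  if (is.null(taxa)) stop("taxon labels are required")
  taxa <- gsub("[ \t]+", "_", as.character(taxa))  # newick-safe labels
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1L])
  }
  if (length(taxa) != nrow(tokens)) {
    stop("number of taxon labels (", length(taxa),
         ") does not match number of rows (", nrow(tokens), ")")
  }
  n_char <- ncol(tokens)
  bad <- !grepl("^([0-9]+|\\?|-)$", tokens)
  dim(bad) <- dim(tokens)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("invalid state token '", tokens[bad][1L], "' for taxon '",
         taxa[idx[1L]], "', character ", idx[2L])
  }
  char_type <- rep_len(match.arg(char_type, c("unordered", "ordered"),
                                 several.ok = TRUE), n_char)
  weights <- rep_len(as.integer(weights), n_char)
  if (any(is.na(weights)) || any(weights < 0L)) {
    stop("weights must be non-negative integers")
  }
  # canonicalize polymorphic tokens: sorted unique digits
  poly <- grepl("^[0-9]{2,}$", tokens)
  if (any(poly)) {
    tokens[poly] <- vapply(tokens[poly], function(tk) {
      paste(sort(unique(strsplit(tk, "")[[1L]])), collapse = "")
    }, character(1L))
  }
  m <- structure(
    list(taxa = taxa, tokens = unname(tokens), masks = NULL,
         char_type = char_type, weights = weights,
         n_taxa = length(taxa), n_char = n_char),
    class = "char_matrix")
  m$masks <- normalize_masks(m)
  m
}

# tokens -> normalized bitmask matrix ('?'/'-' become the observed state set)
normalize_masks <- function(m) {
  masks <- matrix(0L, m$n_taxa, m$n_char)
  for (c in seq_len(m$n_char)) {
    col <- m$tokens[, c]
    miss <- col %in% c("?", "-")
    cells <- lapply(col[!miss], function(tk) {
      as.integer(strsplit(tk, "")[[1L]])
    })
    obs <- sort(unique(unlist(cells)))
    obs_mask <- if (length(obs)) states_to_mask(obs) else 1L  # all-missing: {0}
    masks[!miss, c] <- vapply(cells, states_to_mask, integer(1L))
    masks[miss, c] <- obs_mask
  }
  masks
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Character matrix:", x$n_taxa, "taxa x", x$n_char, "characters\n")
  n_ord <- sum(x$char_type == "ordered")
  if (n_ord) {
    cat("  ordered characters:",
        paste(which(x$char_type == "ordered"), collapse = " "), "\n")
  }
  if (any(x$weights != 1L)) cat("  non-unit weights present\n")
  n_miss <- sum(x$tokens %in% c("?", "-"))
  cat("  missing/inapplicable cells:", n_miss,
      sprintf("(%.1f%%)", 100 * n_miss / length(x$tokens)), "\n")
  invisible(x)
}

#' Test two character matrices for equality of scientific content
#'
#' Compares taxa, normalized state sets, character types and weights;
#' ignores the distinction between `?` and `-` (both normalize identically).
#'
#' @param a,b `char_matrix` objects.
#' @return logical.
#' @export
matrices_equal <- function(a, b) {
  stopifnot(inherits(a, "char_matrix"), inherits(b, "char_matrix"))
  identical(a$taxa, b$taxa) && identical(a$masks, b$masks) &&
    identical(a$char_type, b$char_type) && identical(a$weights, b$weights)
}

# validate taxon subset against a matrix, return 0-based row-index bitmask
group_mask <- function(m, group) {
  idx <- match(group, m$taxa)
  if (anyNA(idx)) stop("unknown taxa in group: ",
                       paste(group[is.na(idx)], collapse = ", "))
  if (anyDuplicated(idx)) stop("duplicated taxa in group")
  states_to_mask_wide(idx - 1L)
}

# like states_to_mask but for taxon indices (may exceed bit 9)
states_to_mask_wide <- function(idx) {
  s <- 0
  for (i in idx) s <- s + 2^i
  as.integer(s)
}

mask_to_idx <- function(mask, n) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
}
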
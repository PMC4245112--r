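#' Read a character matrix from TNT- or NEXUS-style text
#'
#' Parses a discrete character matrix from either a TNT `xread` block or a
#' NEXUS `DATA`/`CHARACTERS` block. States are digits 0-9; `?` is missing,
#' `-` inapplicable; polymorphic cells may be written `[01]`, `(01)` or
#' `{01}`. Ordered (additive) character declarations are honoured: TNT
#' `ccode + <0-based indices>;` and NEXUS
#' `TYPESET ... = ord: <1-based list>;`.
#'
#' @param x a file path or the text content itself (a single string or a
#'   character vector of lines).
#' @param dialect `"auto"` (default), `"tnt"` or `"nexus"`.
#' @return a [character_matrix()] object.
#' @export
read_matrix <- function(x, dialect = c("auto", "tnt", "nexus")) {
  dialect <- match.arg(dialect)
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  }
  text <- paste(x, collapse = "\n")
  if (dialect == "auto") {
    dialect <- if (grepl("#NEXUS", text, ignore.case = TRUE)) "nexus"
               else if (grepl("\\bxread\\b", text, ignore.case = TRUE)) "tnt"
               else stop("cannot detect dialect: no '#NEXUS' or 'xread' found")
  }
  switch(dialect, tnt = parse_tnt(text), nexus = parse_nexus(text))
}

# split a state string like "010?[01]2" into cell tokens, 1 per character
tokenize_states <- function(s, taxon) {
  chars <- strsplit(s, "")[[1L]]
  tokens <- character(0L)
  i <- 1L
  closers <- c("[" = "]", "(" = ")", "{" = "}")
  while (i <= length(chars)) {
    ch <- chars[i]
    if (grepl("^[0-9?]$", ch) || ch == "-") {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else if (ch %in% names(closers)) {
      j <- i + 1L
      poly <- character(0L)
      while (j <= length(chars) && chars[j] != closers[[ch]]) {
        if (!grepl("^[0-9]$", chars[j])) {
          stop("invalid symbol '", chars[j], "' inside polymorphism at ",
               "position ", j, " of row for taxon '", taxon, "'")
        }
        poly <- c(poly, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stop("unclosed polymorphism for taxon '",
                                  taxon, "'")
      tokens <- c(tokens, paste(sort(unique(poly)), collapse = ""))
      i <- j + 1L
    } else if (ch %in% c(" ", "\t")) {
      i <- i + 1L
    } else {
      stop("invalid state symbol '", ch, "' at position ", i,
           " of row for taxon '", taxon, "'")
    }
  }
  tokens
}

# expand "3 5 8.10" (TNT, 0-based) or "4 6 9-11" (NEXUS, 1-based) index lists
expand_index_list <- function(s, range_sep) {
  s <- trimws(s)
  if (s == "") return(integer(0L))
  parts <- strsplit(s, "[ \t]+")[[1L]]
  out <- integer(0L)
  for (p in parts) {
    if (grepl(range_sep, p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, range_sep, fixed = TRUE)[[1L]])
      out <- c(out, seq(ab[1L], ab[2L]))
    } else {
      out <- c(out, as.integer(p))
    }
  }
  out
}

parse_tnt <- function(text) {
  text <- gsub("'[^']*'", "", text)            # drop quoted comments
  if (!grepl("\\bxread\\b", text, ignore.case = TRUE)) {
    stop("TNT input lacks an xread block")
  }
  body <- sub(".*?\\bxread\\b", "", text, ignore.case = TRUE)
  block <- strsplit(body, ";", fixed = TRUE)[[1L]][1L]
  lines <- trimws(strsplit(block, "\n")[[1L]])
  lines <- lines[lines != ""]
  dims <- as.integer(strsplit(lines[1L], "[ \t]+")[[1L]])
  if (length(dims) != 2L || anyNA(dims)) {
    stop("expected 'nchar ntax' after xread, got: ", lines[1L])
  }
  n_char <- dims[1L]; n_taxa <- dims[2L]
  rows <- lines[-1L]
  if (length(rows) != n_taxa) {
    stop("expected ", n_taxa, " taxon rows, found ", length(rows))
  }
  taxa <- character(n_taxa)
  tokens <- matrix("", n_taxa, n_char)
  for (r in seq_len(n_taxa)) {
    name <- sub("[ \t].*$", "", rows[r])
    states <- sub("^[^ \t]+[ \t]+", "", rows[r])
    tk <- tokenize_states(states, name)
    if (length(tk) != n_char) {
      stop("taxon '", name, "' has ", length(tk), " characters, expected ",
           n_char)
    }
    taxa[r] <- name
    tokens[r, ] <- tk
  }
  char_type <- rep("unordered", n_char)
  weights <- rep(1L, n_char)
  cc <- regmatches(text, gregexpr("ccode[^;]*;", text, ignore.case = TRUE))[[1L]]
  for (cmd in cc) {
    body <- sub(";\\s*$", "", sub("^[ \t]*ccode", "", cmd, ignore.case = TRUE))
    parts <- strsplit(trimws(body), "[ \t]+")[[1L]]
    mode <- NULL
    wval <- NA_integer_
    for (p in parts) {
      if (p == "+") { mode <- "ordered"; next }
      if (p == "-") { mode <- "unordered"; next }
      if (grepl("^/[0-9]+$", p)) {
        mode <- "weight"; wval <- as.integer(sub("/", "", p)); next
      }
      idx0 <- expand_index_list(p, ".")
      if (any(idx0 < 0L | idx0 >= n_char)) {
        stop("ccode index out of range (TNT indices are 0-based)")
      }
      if (is.null(mode)) stop("ccode indices before any +/-// marker")
      if (mode == "weight") weights[idx0 + 1L] <- wval
      else char_type[idx0 + 1L] <- mode
    }
  }
  character_matrix(tokens, taxa, char_type, weights)
}

parse_nexus <- function(text) {
  dims <- regmatches(text, regexpr(
    "DIMENSIONS[^;]*;", text, ignore.case = TRUE))
  if (!length(dims)) stop("NEXUS input lacks a DIMENSIONS command")
  n_taxa <- as.integer(sub(".*NTAX[ \t]*=[ \t]*([0-9]+).*", "\\1", dims,
                           ignore.case = TRUE))
  n_char <- as.integer(sub(".*NCHAR[ \t]*=[ \t]*([0-9]+).*", "\\1", dims,
                           ignore.case = TRUE))
  if (is.na(n_taxa) || is.na(n_char)) stop("could not parse NTAX/NCHAR")
  mat <- regmatches(text, regexpr(
    "MATRIX[ \t\r\n]+[^;]*;", text, ignore.case = TRUE))
  if (!length(mat)) stop("NEXUS input lacks a MATRIX command")
  lines <- trimws(strsplit(mat, "\n")[[1L]])
  lines <- lines[-1L]                                  # drop 'MATRIX'
  lines <- sub(";\\s*$", "", lines)
  lines <- lines[lines != ""]
  if (length(lines) != n_taxa) {
    stop("expected ", n_taxa, " taxon rows in MATRIX, found ", length(lines))
  }
  taxa <- character(n_taxa)
  tokens <- matrix("", n_taxa, n_char)
  for (r in seq_len(n_taxa)) {
    name <- sub("[ \t].*$", "", lines[r])
    name <- gsub("^'|'$", "", name)
    states <- sub("^[^ \t]+[ \t]+", "", lines[r])
    tk <- tokenize_states(states, name)
    if (length(tk) != n_char) {
      stop("taxon '", name, "' has ", length(tk), " characters, expected ",
           n_char)
    }
    taxa[r] <- name
    tokens[r, ] <- tk
  }
  char_type <- rep("unordered", n_char)
  ts <- regmatches(text, regexpr("TYPESET[^;]*;", text, ignore.case = TRUE))
  if (length(ts)) {
    ord_part <- regmatches(ts, regexpr(
      "\\bord\\b[ \t]*:[ \t]*[0-9][0-9 \t-]*", ts, ignore.case = TRUE))
    if (length(ord_part)) {
      idx1 <- expand_index_list(
        sub(".*:[ \t]*", "", ord_part), "-")
      if (any(idx1 < 1L | idx1 > n_char)) {
        stop("TYPESET index out of range (NEXUS indices are 1-based)")
      }
      char_type[idx1] <- "ordered"
    }
  }
  weights <- rep(1L, n_char)
  ws <- regmatches(text, regexpr("WTSET[^;]*;", text, ignore.case = TRUE))
  if (length(ws)) {
    body <- sub(".*=", "", sub(";\\s*$", "", ws))
    for (grp in strsplit(body, ",", fixed = TRUE)[[1L]]) {
      kv <- strsplit(grp, ":", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("malformed WTSET group: ", grp)
      weights[expand_index_list(kv[2L], "-")] <- as.integer(trimws(kv[1L]))
    }
  }
  character_matrix(tokens, taxa, char_type, weights)
}

#' Write a character matrix as TNT- or NEXUS-style text
#'
#' The output round-trips through [read_matrix()]: polymorphisms, missing
#' (`?`) versus inapplicable (`-`) tokens and ordered-character declarations
#' are all preserved.
#'
#' @param m a [character_matrix()] object.
#' @param dialect `"tnt"` or `"nexus"`.
#' @param file optional path; when given, the text is also written there.
#' @return the matrix text, invisibly when `file` is given.
#' @export
write_matrix <- function(m, dialect = c("tnt", "nexus"), file = NULL) {
  stopifnot(inherits(m, "char_matrix"))
  dialect <- match.arg(dialect)
  if (m$n_taxa == 0L || m$n_char == 0L) stop("empty matrix cannot be written")
  lab <- gsub("[ \t]", "_", m$taxa)
  pad <- formatC(lab, width = max(nchar(lab)) + 2L, flag = "-")
  row_txt <- function(r, brackets) {
    tk <- m$tokens[r, ]
    poly <- nchar(tk) > 1L
    tk[poly] <- paste0(substr(brackets, 1L, 1L), tk[poly],
                       substr(brackets, 2L, 2L))
    paste0(pad[r], paste(tk, collapse = ""))
  }
  ord <- which(m$char_type == "ordered")
  wtab <- split(seq_len(m$n_char), m$weights)
  wtab <- wtab[names(wtab) != "1"]
  if (dialect == "tnt") {
    out <- c("xread", "'matrix written by cladesearch'",
             paste(m$n_char, m$n_taxa),
             vapply(seq_len(m$n_taxa), row_txt, character(1L),
                    brackets = "[]"),
             ";")
    if (length(ord)) {
      out <- c(out, paste0("ccode + ", paste(ord - 1L, collapse = " "), ";"))
    }
    for (w in names(wtab)) {
      out <- c(out, paste0("ccode /", w, " ",
                           paste(wtab[[w]] - 1L, collapse = " "), ";"))
    }
    out <- c(out, "proc/;")
  } else {
    out <- c("#NEXUS", "BEGIN DATA;",
             paste0("  DIMENSIONS NTAX=", m$n_taxa, " NCHAR=", m$n_char, ";"),
             "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
             "  MATRIX",
             paste0("    ",
                    vapply(seq_len(m$n_taxa), row_txt, character(1L),
                           brackets = "{}")),
             "  ;", "END;")
    if (length(ord) || length(wtab)) {
      out <- c(out, "BEGIN ASSUMPTIONS;")
      if (length(ord)) {
        out <- c(out, paste0("  TYPESET * statetypes = ord: ",
                             paste(ord, collapse = " "), ";"))
      }
      if (length(wtab)) {
        out <- c(out, paste0("  WTSET * weights = ",
                             paste(vapply(names(wtab), function(w) {
                               paste0(w, ": ",
                                      paste(wtab[[w]], collapse = " "))
                             }, character(1L)), collapse = ", "), ";"))
      }
      out <- c(out, "END;")
    }
  }
  text <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(text, file)
    return(invisible(text))
  }
  text
}
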
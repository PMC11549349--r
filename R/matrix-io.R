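# Discrete morphological character matrices and their interchange formats
# (TNT xread, NEXUS CHARACTERS). Cells are kept as display tokens ("0",
# "01" for polymorphism, "?" missing, "-" inapplicable) alongside a
# precomputed bitmask encoding used by the tree-length engine.

#' Construct a character-taxon matrix
#'
#' @param taxa character vector of unique taxon names.
#' @param cells character matrix (`length(taxa)` rows) of state tokens:
#'   a digit string such as `"0"`, several digits (`"01"`) for a
#'   polymorphic cell, `"?"` for missing, `"-"` for inapplicable. States
#'   are integers 0-9.
#' @param ordering per-character `"UNORDERED"` (default) or `"ORDERED"`.
#' @param active per-character logical, default all `TRUE`.
#' @param weight per-character positive integer, default 1.
#' @param outgroup optional taxon name used for display rooting.
#' @return object of class `character_matrix`.
#' @export
character_matrix <- function(taxa, cells, ordering = NULL, active = NULL,
                             weight = NULL, outgroup = NULL) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa))
    stop_validation(paste0("duplicate taxon name: ",
                           taxa[duplicated(taxa)][1]))
  cells <- as.matrix(cells)
  if (nrow(cells) != length(taxa))
    stop_validation("cells must have one row per taxon")
  n_char <- ncol(cells)
  ordering <- ordering %||% rep("UNORDERED", n_char)
  active <- active %||% rep(TRUE, n_char)
  weight <- weight %||% rep(1L, n_char)
  stopifnot(length(ordering) == n_char, length(active) == n_char,
            length(weight) == n_char)
  if (any(weight < 1)) stop_validation("character weights must be >= 1")
  if (!all(ordering %in% c("UNORDERED", "ORDERED")))
    stop_validation("ordering must be UNORDERED or ORDERED")
  if (!is.null(outgroup) && !outgroup %in% taxa)
    stop_validation(paste0("outgroup '", outgroup, "' not among taxa"))
  bad <- which(!grepl("^([0-9]+|\\?|-)$", cells))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(cells))
    stop_validation(sprintf("invalid cell token '%s' (taxon %s, character %d)",
                            cells[bad[1]], taxa[i[1]], i[2]))
  }
  rownames(cells) <- taxa
  m <- structure(list(taxa = taxa, n_char = n_char, cells = cells,
                      ordering = ordering, active = active,
                      weight = as.integer(weight), outgroup = outgroup),
                 class = "character_matrix")
  m$masks_info <- compute_masks(m)  # eager: the engine hits this constantly
  m
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("<character_matrix>", length(x$taxa), "taxa x", x$n_char, "characters\n")
  if (!is.null(x$outgroup)) cat("  outgroup:", x$outgroup, "\n")
  n_ord <- sum(x$ordering == "ORDERED")
  if (n_ord) cat(" ", n_ord, "ordered characters\n")
  if (!all(x$active)) cat(" ", sum(!x$active), "inactive characters\n")
  invisible(x)
}

# bitmask encoding: state s -> bit 2^s; 0 means "no information"
# (missing / inapplicable), expanded to full ambiguity by the engine
cell_mask <- function(token) {
  if (token == "?" || token == "-") return(0L)
  states <- as.integer(strsplit(token, "")[[1]])
  Reduce(bitwOr, bitwShiftL(1L, states))
}

# per-cell masks plus per-character observed-state summaries; computed
# once at construction (unscored cells become fully ambiguous over the
# observed states at optimization time)
compute_masks <- function(m) {
  toks <- unique(as.vector(m$cells))
  lut <- vapply(toks, cell_mask, 0L)
  masks <- matrix(lut[m$cells], nrow = length(m$taxa), ncol = m$n_char)
  full <- integer(m$n_char)
  lo <- integer(m$n_char); hi <- integer(m$n_char)
  for (j in seq_len(m$n_char)) {
    u <- Reduce(bitwOr, masks[, j], 0L)
    full[j] <- u
    st <- which(bitwAnd(u, bitwShiftL(1L, 0:30)) != 0L) - 1L
    lo[j] <- if (length(st)) min(st) else 0L
    hi[j] <- if (length(st)) max(st) else 0L
  }
  list(masks = masks, full = full, lo = lo, hi = hi)
}

matrix_masks <- function(m) {
  m$masks_info %||% compute_masks(m)
}

#' Read a TNT xread matrix
#'
#' Accepts the common xread dialect: optional quoted title, `nchar ntaxa`,
#' one `name statestring` row per taxon, closed by `;`. Bracketed groups
#' (`[01]`) are polymorphic cells; `?` is missing and `-` inapplicable.
#' `ccode` statements are honored for ordering (`+`/`-`), activity
#' (`[`/`]`) and integer weights (`/N`), with 0-based character indices
#' and `a.b` ranges, as TNT writes them.
#'
#' @param path file path, or a character vector of lines.
#' @return a [character_matrix()].
#' @export
read_tnt <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else path
  txt <- paste(lines, collapse = "\n")
  m <- regmatches(txt, regexpr("xread.*?;", txt, ignore.case = TRUE))
  if (!length(m)) stop_validation("no xread block found")
  body <- sub("^xread", "", m, ignore.case = TRUE)
  body <- sub(";$", "", body)
  body <- gsub("'[^']*'", "", body)  # strip title
  toks <- strsplit(trimws(body), "\\s+")[[1]]
  if (length(toks) < 2) stop_validation("xread block too short")
  n_char <- as.integer(toks[1]); n_taxa <- as.integer(toks[2])
  if (is.na(n_char) || is.na(n_taxa))
    stop_validation("xread header must be '<nchar> <ntaxa>'")
  toks <- toks[-(1:2)]
  if (length(toks) != 2 * n_taxa)
    stop_validation("expected one 'name states' pair per taxon")
  taxa <- toks[seq(1, length(toks), by = 2)]
  rows <- toks[seq(2, length(toks), by = 2)]
  if (anyDuplicated(taxa))
    stop_validation(paste0("duplicate taxon name: ",
                           taxa[duplicated(taxa)][1]))
  cells <- matrix("?", n_taxa, n_char)
  for (i in seq_len(n_taxa)) {
    tok <- parse_statestring(rows[i], group_open = "[", group_close = "]")
    if (length(tok) != n_char)
      stop_validation(sprintf(
        "row for taxon %s has %d characters, expected %d (near column %d)",
        taxa[i], length(tok), n_char, min(length(tok), n_char) + 1L))
    cells[i, ] <- tok
  }
  cm <- character_matrix(taxa, cells)
  apply_ccode(cm, txt)
}

# split a TNT/NEXUS state row into per-character tokens
parse_statestring <- function(s, group_open, group_close) {
  chars <- strsplit(s, "")[[1]]
  out <- character(0); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == group_open || ch == "(" || ch == "{") {
      close <- if (ch == "(") ")" else if (ch == "{") "}" else group_close
      j <- i + 1L
      grp <- character(0)
      while (j <= length(chars) && chars[j] != close) {
        if (chars[j] != " ") grp <- c(grp, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stop_validation("unclosed polymorphism group")
      out <- c(out, paste(sort(grp), collapse = ""))
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

# apply TNT ccode statements to a parsed matrix
apply_ccode <- function(cm, txt) {
  cc <- regmatches(txt, gregexpr("ccode[^;]*;", txt, ignore.case = TRUE))[[1]]
  for (stmt in cc) {
    toks <- strsplit(trimws(gsub("ccode|;", "", stmt, ignore.case = TRUE)),
                     "\\s+")[[1]]
    mode <- NULL; wt <- NULL
    for (tk in toks) {
      if (tk %in% c("+", "-", "[", "]")) { mode <- tk; next }
      if (grepl("^/", tk)) { wt <- as.integer(sub("^/", "", tk)); next }
      idx <- if (grepl("\\.", tk)) {
        ab <- as.integer(strsplit(tk, "\\.")[[1]]); seq(ab[1], ab[2])
      } else as.integer(tk)
      idx <- idx + 1L  # TNT indices are 0-based
      if (!is.null(wt)) { cm$weight[idx] <- wt; wt <- NULL }
      if (is.null(mode)) next
      if (mode == "+") cm$ordering[idx] <- "ORDERED"
      if (mode == "-") cm$ordering[idx] <- "UNORDERED"
      if (mode == "[") cm$active[idx] <- TRUE
      if (mode == "]") cm$active[idx] <- FALSE
    }
  }
  cm
}

#' Write a matrix as TNT xread
#' @param cm a [character_matrix()].
#' @param path output path.
#' @param title optional quoted title line.
#' @return `path`, invisibly.
#' @export
write_tnt <- function(cm, path, title = NULL) {
  fmt_cell <- function(tok) {
    if (nchar(tok) > 1 && !tok %in% c("?", "-")) paste0("[", tok, "]") else tok
  }
  rows <- vapply(seq_along(cm$taxa), function(i)
    paste0(cm$taxa[i], "  ",
           paste(vapply(cm$cells[i, ], fmt_cell, ""), collapse = "")), "")
  out <- c("xread",
           if (!is.null(title)) paste0("'", title, "'"),
           paste(cm$n_char, length(cm$taxa)),
           rows, ";")
  ord <- which(cm$ordering == "ORDERED")
  if (length(ord))
    out <- c(out, paste0("ccode + ", paste(ord - 1L, collapse = " "), ";"))
  inact <- which(!cm$active)
  if (length(inact))
    out <- c(out, paste0("ccode ] ", paste(inact - 1L, collapse = " "), ";"))
  out <- c(out, "proc /;")
  writeLines(out, path)
  invisible(path)
}

#' Read a NEXUS DATA/CHARACTERS block
#'
#' Minimal standard-data NEXUS reader: honors `DIMENSIONS NTAX/NCHAR`,
#' `FORMAT SYMBOLS/MISSING/GAP`, and polymorphic groups written as
#' `(01)`, `(0 1)` or `{01}`. Symbols are mapped to integer states by
#' their position in the SYMBOLS declaration (or taken as digits when no
#' declaration is present); undeclared symbols in the matrix are an error.
#'
#' @param path file path or character vector of lines.
#' @return a [character_matrix()].
#' @export
read_nexus <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else path
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)  # NEXUS comments
  get1 <- function(pat) {
    m <- regmatches(txt, regexpr(pat, txt, ignore.case = TRUE, perl = TRUE))
    if (length(m)) m else NULL
  }
  ntax <- as.integer(sub(".*=", "", get1("NTAX\\s*=\\s*\\d+") %||%
                           stop_validation("NTAX not found")))
  nchr <- as.integer(sub(".*=", "", get1("NCHAR\\s*=\\s*\\d+") %||%
                           stop_validation("NCHAR not found")))
  sym <- get1("SYMBOLS\\s*=\\s*\"[^\"]*\"")
  symbols <- if (is.null(sym)) as.character(0:9)
             else strsplit(gsub("\\s", "", sub(".*\"([^\"]*)\".*", "\\1", sym)),
                           "")[[1]]
  missing_ch <- sub(".*=\\s*", "", get1("MISSING\\s*=\\s*\\S") %||% "=?")
  gap_ch <- sub(".*=\\s*", "", get1("GAP\\s*=\\s*\\S") %||% "=-")
  mm <- regmatches(txt, regexpr("(?s)MATRIX\\s(.*?);", txt,
                                ignore.case = TRUE, perl = TRUE))
  if (!length(mm)) stop_validation("MATRIX block not found")
  body <- sub("^MATRIX", "", mm, ignore.case = TRUE)
  body <- sub(";$", "", body)
  rows <- trimws(strsplit(body, "\n")[[1]])
  rows <- rows[nzchar(rows)]
  if (length(rows) != ntax)
    stop_validation(sprintf("MATRIX has %d rows, NTAX=%d",
                            length(rows), ntax))
  taxa <- character(ntax)
  cells <- matrix("?", ntax, nchr)
  sym_to_state <- function(ch, taxon) {
    if (ch == missing_ch) return("?")
    if (ch == gap_ch) return("-")
    k <- match(ch, symbols)
    if (is.na(k))
      stop_validation(sprintf("undeclared symbol '%s' in row for %s",
                              ch, taxon))
    as.character(k - 1L)
  }
  for (i in seq_len(ntax)) {
    parts <- strsplit(rows[i], "\\s+")[[1]]
    taxa[i] <- gsub("^'|'$", "", parts[1])
    states <- paste(parts[-1], collapse = "")
    tok <- parse_statestring(states, group_open = "{", group_close = "}")
    if (length(tok) != nchr)
      stop_validation(sprintf(
        "row for taxon %s has %d characters, NCHAR=%d",
        taxa[i], length(tok), nchr))
    cells[i, ] <- vapply(tok, function(t) {
      if (nchar(t) == 1) sym_to_state(t, taxa[i])
      else paste(sort(vapply(strsplit(t, "")[[1]], sym_to_state, "",
                             taxon = taxa[i])), collapse = "")
    }, "")
  }
  character_matrix(taxa, cells)
}

#' Write a matrix as a NEXUS CHARACTERS block
#' @param cm a [character_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(cm, path) {
  mx <- max(c(1L, as.integer(unlist(strsplit(
    cm$cells[!cm$cells %in% c("?", "-")], "")))))
  fmt_cell <- function(tok) {
    if (nchar(tok) > 1 && !tok %in% c("?", "-")) paste0("(", tok, ")") else tok
  }
  rows <- vapply(seq_along(cm$taxa), function(i)
    paste0("  ", cm$taxa[i], "  ",
           paste(vapply(cm$cells[i, ], fmt_cell, ""), collapse = "")), "")
  out <- c("#NEXUS", "BEGIN DATA;",
           sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(cm$taxa), cm$n_char),
           sprintf("FORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;",
                   paste(0:mx, collapse = " ")),
           "MATRIX", rows, ";", "END;")
  writeLines(out, path)
  invisible(path)
}
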
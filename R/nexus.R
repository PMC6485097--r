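# NEXUS I/O for morphological (STANDARD datatype) matrices.
#
# Hand-written on purpose: the package's semantics require every cell to be
# a state *set* (polymorphism as uncertainty, gap distinguished from '?'
# only for round-tripping), which generic NEXUS readers flatten.

#' Read a morphological matrix from a NEXUS document
#'
#' Supports a CHARACTERS or DATA block with DIMENSIONS, FORMAT
#' (SYMBOLS/MISSING/GAP) and MATRIX commands, plus an optional ASSUMPTIONS
#' block with TYPESET (`ord:`/`unord:`) and WTSET commands.  Polymorphic
#' cells may be written `{01}`, `{0 1}` or `(01)`.  The inapplicable symbol
#' (gap, default `-`) is treated as missing for all computations; its
#' position is remembered so the document round-trips.
#'
#' @param file path to a NEXUS file, or the document itself as a character
#'   string (anything containing a newline or starting with `#NEXUS`).
#' @return a [char_matrix()]
#' @examples
#' nx <- "#NEXUS
#' BEGIN DATA;
#' DIMENSIONS NTAX=2 NCHAR=3;
#' FORMAT DATATYPE=STANDARD SYMBOLS=\"012\" MISSING=? GAP=-;
#' MATRIX
#' A 01{02}
#' B 1?-
#' ;
#' END;"
#' read_nexus(nx)
#' @export
read_nexus <- function(file) {
  txt <- slurp_text(file, "#NEXUS")
  if (!grepl("#NEXUS", txt, ignore.case = TRUE))
    stop("not a NEXUS document (missing #NEXUS header)")
  txt_nc <- strip_nexus_comments(txt)

  blk <- extract_block(txt_nc, c("CHARACTERS", "DATA"))
  if (is.null(blk)) stop("no CHARACTERS or DATA block found")

  dm <- regmatches(blk, regexpr("(?is)DIMENSIONS[^;]*;", blk, perl = TRUE))
  if (!length(dm)) stop("DIMENSIONS command missing")
  ntax <- cmd_int(dm, "NTAX"); nchar <- cmd_int(dm, "NCHAR")
  if (is.na(nchar)) stop("DIMENSIONS must declare NCHAR")

  fmt <- regmatches(blk, regexpr("(?is)FORMAT[^;]*;", blk, perl = TRUE))
  missing_char <- cmd_char(fmt, "MISSING", "?")
  gap_char <- cmd_char(fmt, "GAP", "-")
  symbols <- cmd_string(fmt, "SYMBOLS")
  allowed <- if (!is.null(symbols)) strsplit(gsub("\\s", "", symbols), "")[[1]] else NULL

  mtx <- regmatches(blk, regexpr("(?is)MATRIX(.*?);", blk, perl = TRUE))
  if (!length(mtx)) stop("MATRIX command missing")
  body <- sub("(?is)^MATRIX", "", mtx, perl = TRUE)
  body <- sub(";\\s*$", "", body)

  rows <- parse_matrix_body(body, nchar, missing_char, gap_char, allowed)
  if (!is.na(ntax) && length(rows$taxa) != ntax)
    stop("DIMENSIONS declares NTAX=", ntax, " but MATRIX has ",
         length(rows$taxa), " taxa")

  m <- cells_to_matrix(rows$taxa, rows$cells, nchar)

  ass <- extract_block(txt_nc, "ASSUMPTIONS")
  if (!is.null(ass)) m <- apply_assumptions(m, ass)
  m
}

#' Write a matrix as a NEXUS document
#'
#' Inverse of [read_nexus()]: `read_nexus(write_nexus(m))` reproduces `m`
#' exactly (taxa, state sets, specs, and the missing/inapplicable
#' distinction).  Ordered characters and non-unit weights are emitted as an
#' ASSUMPTIONS block (TYPESET / WTSET).
#'
#' @param m a [char_matrix()]
#' @param file optional path; when `NULL` the document is returned as a
#'   string.
#' @return the document, invisibly when written to `file`
#' @export
write_nexus <- function(m, file = NULL) {
  stopifnot(inherits(m, "char_matrix"))
  if (n_taxa(m) == 0L) stop("cannot write a matrix with no taxa")
  max_sym <- max(m$specs$max_state)
  wid <- max(nchar(m$taxa)) + 2L
  rows <- vapply(seq_len(n_taxa(m)), function(i) {
    toks <- vapply(seq_len(n_char(m)), function(j) {
      format_cell_token(bits_to_states(m$bits[i, j]), m$missing[i, j],
                        m$gap[i, j], style = "nexus")
    }, character(1))
    sprintf("%-*s%s", wid, m$taxa[i], paste(toks, collapse = ""))
  }, character(1))
  out <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(m), n_char(m)),
    sprintf("FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
            paste(0:max_sym, collapse = "")),
    "MATRIX",
    rows,
    ";",
    "END;"
  )
  ord <- which(m$specs$ordered)
  wts <- m$specs$weight
  if (length(ord) || any(wts != 1)) {
    ass <- "BEGIN ASSUMPTIONS;"
    if (length(ord)) {
      unord <- setdiff(seq_len(n_char(m)), ord)
      parts <- sprintf("ord: %s", paste(ord, collapse = " "))
      if (length(unord))
        parts <- c(parts, sprintf("unord: %s", paste(unord, collapse = " ")))
      ass <- c(ass, sprintf("TYPESET * default = %s;", paste(parts, collapse = ", ")))
    }
    if (any(wts != 1)) {
      grp <- split(seq_len(n_char(m)), wts)
      ass <- c(ass, sprintf("WTSET * default = %s;",
                            paste(vapply(names(grp), function(w) {
                              sprintf("%s: %s", w, paste(grp[[w]], collapse = " "))
                            }, character(1)), collapse = ", ")))
    }
    out <- c(out, ass, "END;")
  }
  doc <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

## ---- shared parsing helpers -------------------------------------------

slurp_text <- function(file, magic) {
  if (length(file) == 1L && !grepl("\n", file) &&
      !startsWith(trimws(file), magic) && file.exists(file)) {
    return(paste(readLines(file, warn = FALSE), collapse = "\n"))
  }
  paste(file, collapse = "\n")
}

strip_nexus_comments <- function(txt) gsub("\\[[^]]*\\]", "", txt)

extract_block <- function(txt, names) {
  for (nm in names) {
    rx <- paste0("(?is)BEGIN\\s+", nm, "\\s*;(.*?)\\bEND\\s*;")
    hit <- regmatches(txt, regexpr(rx, txt, perl = TRUE))
    if (length(hit)) return(sub(rx, "\\1", hit, perl = TRUE))
  }
  NULL
}

cmd_int <- function(cmd, key) {
  if (!length(cmd)) return(NA_integer_)
  rx <- paste0("(?i)", key, "\\s*=\\s*(\\d+)")
  hit <- regmatches(cmd, regexpr(rx, cmd, perl = TRUE))
  if (!length(hit)) return(NA_integer_)
  as.integer(sub(rx, "\\1", hit, perl = TRUE))
}

cmd_char <- function(cmd, key, default) {
  if (!length(cmd)) return(default)
  rx <- paste0("(?i)", key, "\\s*=\\s*(\\S)")
  hit <- regmatches(cmd, regexpr(rx, cmd, perl = TRUE))
  if (!length(hit)) return(default)
  sub(rx, "\\1", hit, perl = TRUE)
}

cmd_string <- function(cmd, key) {
  if (!length(cmd)) return(NULL)
  rx <- paste0("(?i)", key, "\\s*=\\s*\"([^\"]*)\"")
  hit <- regmatches(cmd, regexpr(rx, cmd, perl = TRUE))
  if (!length(hit)) return(NULL)
  sub(rx, "\\1", hit, perl = TRUE)
}

# Split a row of state symbols (possibly with {..} / (..) / [..] groups)
# into cell tokens.
split_state_string <- function(s, openers = c("{", "(", "["),
                               closers = c("}", ")", "]")) {
  chars <- strsplit(s, "")[[1]]
  toks <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% openers) {
      close <- closers[match(ch, openers)]
      j <- i + 1L
      while (j <= length(chars) && chars[j] != close) j <- j + 1L
      if (j > length(chars)) stop("unclosed '", ch, "' in matrix row")
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  toks
}

# Parse a MATRIX body (possibly interleaved) into taxa + token rows.
parse_matrix_body <- function(body, nchar, missing_char, gap_char, allowed) {
  lines <- strsplit(body, "\n")[[1]]
  taxa <- character(0)
  cells <- list()
  for (ln_no in seq_along(lines)) {
    ln <- trimws(lines[ln_no])
    if (!nzchar(ln)) next
    # label: quoted or up to first whitespace
    if (startsWith(ln, "'") || startsWith(ln, "\"")) {
      q <- substr(ln, 1L, 1L)
      end <- regexpr(paste0(q, "(?!", q, ")"), substring(ln, 2L), perl = TRUE)
      if (end < 0) stop("unterminated quoted label at matrix line ", ln_no)
      label <- substr(ln, 2L, end)
      rest <- substring(ln, end + 2L)
    } else {
      sp <- regexpr("[[:space:]]", ln)
      if (sp < 0) stop("matrix line ", ln_no, " has a label but no states: '", ln, "'")
      label <- substr(ln, 1L, sp - 1L)
      rest <- substring(ln, sp + 1L)
    }
    label <- normalize_label(label)
    toks <- split_state_string(rest)
    if (!is.null(allowed)) {
      syms <- unlist(strsplit(toks, ""))
      syms <- setdiff(syms, c("{", "}", "(", ")", "[", "]", " ", "/", ","))
      bad <- setdiff(syms, c(allowed, missing_char, gap_char))
      if (length(bad))
        stop("undeclared symbol '", bad[1], "' for taxon ", label,
             " at matrix line ", ln_no)
    }
    k <- match(label, taxa)
    if (is.na(k)) {
      taxa <- c(taxa, label)
      cells[[length(taxa)]] <- toks
    } else {
      if (length(cells[[k]]) >= nchar)
        stop("duplicate taxon ", label, " at matrix line ", ln_no)
      cells[[k]] <- c(cells[[k]], toks)  # interleaved continuation
    }
  }
  got <- lengths(cells)
  if (any(got != nchar))
    stop("taxon ", taxa[which(got != nchar)[1]], " has ",
         got[which(got != nchar)[1]], " cells, expected ", nchar)
  list(taxa = taxa, cells = cells)
}

cells_to_matrix <- function(taxa, cells, nchar,
                            missing_char = "?", gap_char = "-") {
  grid <- matrix("", length(taxa), nchar)
  for (i in seq_along(taxa)) grid[i, ] <- cells[[i]]
  rownames(grid) <- taxa
  char_matrix(grid)
}

# ASSUMPTIONS block: TYPESET ord/unord lists, WTSET weight groups.
apply_assumptions <- function(m, blk) {
  ts <- regmatches(blk, regexpr("(?is)TYPESET[^;]*;", blk, perl = TRUE))
  if (length(ts)) {
    spec <- sub("(?is)^TYPESET[^=]*=", "", ts, perl = TRUE)
    for (part in strsplit(sub(";\\s*$", "", spec), ",")[[1]]) {
      kv <- strsplit(trimws(part), ":")[[1]]
      if (length(kv) != 2L) next
      idx <- parse_index_list(kv[2], n_char(m))
      kind <- tolower(trimws(kv[1]))
      if (kind %in% c("ord", "ordered"))
        m <- set_ordered(m, TRUE, idx)
      else if (kind %in% c("unord", "unordered"))
        m <- set_ordered(m, FALSE, idx)
    }
  }
  ws <- regmatches(blk, regexpr("(?is)WTSET[^;]*;", blk, perl = TRUE))
  if (length(ws)) {
    spec <- sub("(?is)^WTSET[^=]*=", "", ws, perl = TRUE)
    for (part in strsplit(sub(";\\s*$", "", spec), ",")[[1]]) {
      kv <- strsplit(trimws(part), ":")[[1]]
      if (length(kv) != 2L) next
      w <- as.numeric(trimws(kv[1]))
      m <- set_weights(m, w, parse_index_list(kv[2], n_char(m)))
    }
  }
  m
}

# "2 4-6 9" -> c(2, 4, 5, 6, 9); "ALL" -> every character
parse_index_list <- function(s, nchar) {
  s <- trimws(s)
  if (toupper(s) == "ALL") return(seq_len(nchar))
  out <- integer(0)
  for (tok in strsplit(s, "[[:space:]]+")[[1]]) {
    if (grepl("^\\d+-\\d+$", tok)) {
      ab <- as.integer(strsplit(tok, "-")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^\\d+$", tok)) {
      out <- c(out, as.integer(tok))
    }
  }
  out[out >= 1L & out <= nchar]
}
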
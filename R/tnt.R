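# TNT `xread` dialect: header `nchar ntax`, rows of label + state string,
# `[01]`-style polymorphism, terminated by `;`.  An optional `ccode`
# command (subset: `+` marks additive/ordered characters, `/w` sets
# weights; indices 0-based as in TNT) carries the character specs.

#' Read a morphological matrix in TNT xread format
#'
#' @param file path to a TNT file, or the document as a string.
#' @return a [char_matrix()]
#' @examples
#' read_tnt("xread\n3 2\nA 01[01]\nB 1?0\n;")
#' @export
read_tnt <- function(file) {
  txt <- slurp_text(file, "xread")
  if (!grepl("(?i)xread", txt, perl = TRUE)) stop("not a TNT xread document")
  body <- sub("(?is)^.*?xread", "", txt, perl = TRUE)
  # optional quoted title
  body <- sub("^\\s*'[^']*'", "", body)
  hdr <- regmatches(body, regexpr("^\\s*(\\d+)\\s+(\\d+)", body, perl = TRUE))
  if (!length(hdr)) stop("xread header must give nchar and ntax")
  nums <- as.integer(strsplit(trimws(hdr), "\\s+")[[1]])
  nchar <- nums[1]; ntax <- nums[2]
  body <- sub("^\\s*\\d+\\s+\\d+", "", body)
  semi <- regexpr(";", body, fixed = TRUE)
  if (semi < 0) stop("xread block not terminated by ';'")
  mat_body <- substr(body, 1L, semi - 1L)
  rest <- substring(body, semi + 1L)

  rows <- parse_matrix_body(mat_body, nchar, "?", "-", allowed = NULL)
  if (length(rows$taxa) != ntax)
    stop("xread header declares ntax=", ntax, " but matrix has ",
         length(rows$taxa), " taxa")
  m <- cells_to_matrix(rows$taxa, rows$cells, nchar)
  apply_ccode(m, rest)
}

#' Write a matrix in TNT xread format
#'
#' Inverse of [read_tnt()]; ordered characters and non-unit weights are
#' emitted as `ccode` commands (0-based indices, TNT convention).
#'
#' @inheritParams write_nexus
#' @return the document, invisibly when written to `file`
#' @export
write_tnt <- function(m, file = NULL) {
  stopifnot(inherits(m, "char_matrix"))
  if (n_taxa(m) == 0L) stop("cannot write a matrix with no taxa")
  wid <- max(nchar(m$taxa)) + 2L
  rows <- vapply(seq_len(n_taxa(m)), function(i) {
    toks <- vapply(seq_len(n_char(m)), function(j) {
      format_cell_token(bits_to_states(m$bits[i, j]), m$missing[i, j],
                        m$gap[i, j], style = "tnt")
    }, character(1))
    sprintf("%-*s%s", wid, m$taxa[i], paste(toks, collapse = ""))
  }, character(1))
  out <- c("xread", sprintf("%d %d", n_char(m), n_taxa(m)), rows, ";")
  ord <- which(m$specs$ordered)
  if (length(ord))
    out <- c(out, sprintf("ccode + %s;", paste(ord - 1L, collapse = " ")))
  wts <- m$specs$weight
  if (any(wts != 1)) {
    grp <- split(seq_len(n_char(m)) - 1L, wts)
    for (w in names(grp))
      out <- c(out, sprintf("ccode /%s %s;", w, paste(grp[[w]], collapse = " ")))
  }
  doc <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

apply_ccode <- function(m, rest) {
  for (cmd in regmatches(rest, gregexpr("(?is)ccode[^;]*;", rest, perl = TRUE))[[1]]) {
    spec <- trimws(sub(";\\s*$", "", sub("(?i)^\\s*ccode", "", cmd, perl = TRUE)))
    # "+ 1 2" (additive), "/w 3 4" (weight)
    if (startsWith(spec, "+")) {
      idx0 <- parse_index_list0(sub("^\\+", "", spec)) + 1L  # TNT is 0-based
      m <- set_ordered(m, TRUE, idx0[idx0 >= 1L & idx0 <= n_char(m)])
    } else if (startsWith(spec, "/")) {
      body <- sub("^/", "", spec)
      parts <- strsplit(trimws(body), "\\s+")[[1]]
      w <- as.numeric(parts[1])
      idx0 <- parse_index_list0(paste(parts[-1], collapse = " ")) + 1L
      m <- set_weights(m, w, idx0[idx0 >= 1L & idx0 <= n_char(m)])
    }
  }
  m
}

# 0-based index list, space-separated, "a-b" ranges allowed
parse_index_list0 <- function(s) {
  out <- integer(0)
  for (tok in strsplit(trimws(s), "[[:space:]]+")[[1]]) {
    if (grepl("^\\d+-\\d+$", tok)) {
      ab <- as.integer(strsplit(tok, "-")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^\\d+$", tok)) {
      out <- c(out, as.integer(tok))
    }
  }
  out
}
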
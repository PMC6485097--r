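#' Discrete morphological character matrix
#'
#' A `char_matrix` holds a taxa-by-characters grid of state *sets*: each
#' cell is the set of integer states admissible for that taxon and
#' character.  Singleton sets are ordinary observations, larger sets are
#' polymorphic/uncertain codings such as `(0/1)`, and missing (`?`) or
#' inapplicable (`-`) cells resolve to the full state range of their
#' character.  Per-character specifications carry the maximum state, the
#' ordered flag (Wagner vs Fitch optimization) and a positive weight.
#'
#' @param cells character matrix of cell tokens (rows = taxa, columns =
#'   characters).  Tokens follow morphological matrix conventions: `"0"`,
#'   `"?"`, `"-"`, `"{0 1}"`, `"(01)"`, `"[01]"` or `"0/1"`.  Row names (or
#'   `taxa`) give the taxon labels.
#' @param taxa character vector of taxon labels; defaults to
#'   `rownames(cells)`.
#' @param ordered logical, recycled over characters: optimize as ordered
#'   (Wagner) characters with cost `|i - j|`?  Default all unordered.
#' @param weights positive numeric, recycled over characters.  Default 1.
#' @return an object of class `char_matrix` with fields `taxa`, `bits`
#'   (bitmask grid), `missing` and `gap` (logical grids) and `specs`
#'   (data frame: `char`, `max_state`, `ordered`, `weight`).
#' @examples
#' m <- char_matrix(rbind(A = c("0", "0"), B = c("1", "{0 1}")))
#' m
#' @export
char_matrix <- function(cells, taxa = rownames(cells), ordered = FALSE,
                        weights = 1) {
  if (is.null(dim(cells))) cells <- matrix(cells, ncol = 1L)
  if (is.null(taxa)) stop("taxon labels are required (rownames or `taxa`)")
  ntax <- nrow(cells); nchar <- ncol(cells)
  sets <- vector("list", ntax * nchar)
  miss <- gap <- matrix(FALSE, ntax, nchar)
  for (j in seq_len(nchar)) {
    for (i in seq_len(ntax)) {
      v <- parse_cell_token(as.character(cells[i, j]))
      if (length(v) == 1L && is.na(v[1])) {
        miss[i, j] <- TRUE
        gap[i, j] <- identical(attr(v, "kind"), "gap")
        sets[[(j - 1L) * ntax + i]] <- NA
      } else {
        sets[[(j - 1L) * ntax + i]] <- v
      }
    }
  }
  max_state <- integer(nchar)
  bits <- matrix(0L, ntax, nchar)
  for (j in seq_len(nchar)) {
    obs <- unlist(lapply(seq_len(ntax), function(i) {
      s <- sets[[(j - 1L) * ntax + i]]
      if (length(s) == 1L && is.na(s[1])) NULL else s
    }))
    max_state[j] <- if (length(obs)) max(obs) else 1L
    if (max_state[j] < 1L) max_state[j] <- 1L
    for (i in seq_len(ntax)) {
      s <- sets[[(j - 1L) * ntax + i]]
      bits[i, j] <- if (miss[i, j]) full_range_bits(max_state[j]) else states_to_bits(s)
    }
  }
  new_char_matrix(normalize_label(taxa), bits, miss, gap,
                  max_state = max_state,
                  ordered = rep_len(as.logical(ordered), nchar),
                  weight = rep_len(as.numeric(weights), nchar))
}

new_char_matrix <- function(taxa, bits, missing, gap, max_state, ordered,
                            weight) {
  m <- structure(list(
    taxa = as.character(taxa),
    bits = bits,
    missing = missing,
    gap = gap,
    specs = data.frame(char = seq_len(ncol(bits)), max_state = max_state,
                       ordered = ordered, weight = weight)
  ), class = "char_matrix")
  validate_char_matrix(m)
}

validate_char_matrix <- function(m) {
  ntax <- length(m$taxa); nchar <- nrow(m$specs)
  if (anyDuplicated(m$taxa))
    stop("duplicate taxon label: ",
         paste(unique(m$taxa[duplicated(m$taxa)]), collapse = ", "))
  stopifnot(nrow(m$bits) == ntax, ncol(m$bits) == nchar,
            identical(dim(m$missing), dim(m$bits)),
            identical(dim(m$gap), dim(m$bits)),
            all(m$specs$weight > 0), all(m$specs$max_state >= 1))
  for (j in seq_len(nchar)) {
    full <- full_range_bits(m$specs$max_state[j])
    if (any(m$bits[, j] == 0L))
      stop("empty state set in character ", j)
    if (any(bitwAnd(m$bits[, j], bitwNot(full)) != 0L))
      stop("state above declared max_state in character ", j)
    if (any(m$bits[m$missing[, j], j] != full))
      stop("missing cell not resolved to full range in character ", j)
  }
  m
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("char_matrix:", n_taxa(x), "taxa x", n_char(x), "characters\n")
  cat("  ordered:", sum(x$specs$ordered), "| missing cells:",
      sum(x$missing), sprintf("(%.1f%%)", 100 * mean(x$missing)),
      "| polymorphic cells:", sum(cell_sizes(x) > 1L & !x$missing), "\n")
  cat("  taxa:", paste(head(x$taxa, 5L), collapse = ", "),
      if (n_taxa(x) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Matrix dimensions and cell access
#'
#' @param m a [char_matrix()]
#' @return `n_taxa()`/`n_char()` return integers; `state_set()` the integer
#'   state vector of one cell; `matrix_column()` the list of state sets of
#'   one character (named by taxon, `NA` entries flagged missing).
#' @export
n_taxa <- function(m) length(m$taxa)

#' @rdname n_taxa
#' @export
n_char <- function(m) nrow(m$specs)

#' @rdname n_taxa
#' @param taxon taxon label or index
#' @param char character index (1-based)
#' @export
state_set <- function(m, taxon, char) {
  i <- if (is.character(taxon)) match(taxon, m$taxa) else as.integer(taxon)
  if (is.na(i) || i < 1L || i > n_taxa(m)) stop("unknown taxon: ", taxon)
  bits_to_states(m$bits[i, char])
}

#' @rdname n_taxa
#' @export
matrix_column <- function(m, char) {
  col <- lapply(seq_len(n_taxa(m)), function(i) bits_to_states(m$bits[i, char]))
  names(col) <- m$taxa
  attr(col, "missing") <- m$missing[, char]
  attr(col, "max_state") <- m$specs$max_state[char]
  col
}

cell_sizes <- function(m) {
  matrix(vapply(as.vector(m$bits), function(b) length(bits_to_states(b)),
                integer(1)), nrow(m$bits), ncol(m$bits))
}

#' Subset a character matrix
#'
#' @param m a [char_matrix()]
#' @param taxa taxon labels or indices to keep (default all)
#' @param chars character indices to keep, possibly with repeats (the
#'   bootstrap resamples characters with replacement)
#' @return a new `char_matrix`
#' @export
subset_matrix <- function(m, taxa = NULL, chars = NULL) {
  i <- if (is.null(taxa)) seq_len(n_taxa(m)) else {
    idx <- if (is.character(taxa)) match(normalize_label(taxa), m$taxa) else as.integer(taxa)
    if (anyNA(idx)) stop("unknown taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
    idx
  }
  j <- if (is.null(chars)) seq_len(n_char(m)) else as.integer(chars)
  if (any(j < 1L | j > n_char(m))) stop("character index out of range")
  new_char_matrix(m$taxa[i], m$bits[i, j, drop = FALSE],
                  m$missing[i, j, drop = FALSE], m$gap[i, j, drop = FALSE],
                  max_state = m$specs$max_state[j],
                  ordered = m$specs$ordered[j], weight = m$specs$weight[j])
}

#' Set the ordered flag on characters
#'
#' @param m a [char_matrix()]
#' @param ordered logical, recycled over characters
#' @param chars indices to modify (default all)
#' @return the modified matrix
#' @export
set_ordered <- function(m, ordered = TRUE, chars = seq_len(n_char(m))) {
  m$specs$ordered[chars] <- rep_len(as.logical(ordered), length(chars))
  m
}

#' @rdname set_ordered
#' @param weights positive numeric, recycled
#' @export
set_weights <- function(m, weights, chars = seq_len(n_char(m))) {
  stopifnot(all(weights > 0))
  m$specs$weight[chars] <- rep_len(as.numeric(weights), length(chars))
  m
}

# Equality on scientific content (taxa, state sets, specs); gap provenance
# is compared separately where round-tripping is at stake.
matrices_equal <- function(a, b) {
  identical(a$taxa, b$taxa) &&
    identical(a$bits, b$bits) &&
    identical(a$missing, b$missing) &&
    isTRUE(all.equal(a$specs, b$specs))
}
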
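# Recoding ledgers: documented, replayable edits to a character matrix.
# Each entry names a taxon, a 1-based character, the expected old state
# set, the new state set, and a free-text source note.  State sets are
# written "1", "0/1" or "?"; the old state may be "*" (match anything)
# for edits whose published description does not print the prior coding.

#' Construct a recoding ledger
#'
#' @param taxon character, taxon labels
#' @param char integer, 1-based character indices (as printed in papers:
#'   "ch. 27")
#' @param old expected current state of each cell, as strings (`"1"`,
#'   `"0/1"`, `"?"`, or `"*"` to accept any current state)
#' @param new replacement state, same notation (no `"*"`)
#' @param note free-text provenance note
#' @return a data frame of class `recoding_ledger`
#' @examples
#' recoding_ledger("Aetomylaeus", 27, "1", "2", "mesopterygium absent/fused")
#' @export
recoding_ledger <- function(taxon, char, old, new, note = "") {
  df <- data.frame(taxon = normalize_label(as.character(taxon)),
                   char = as.integer(char),
                   old = as.character(old), new = as.character(new),
                   note = rep_len(as.character(note), length(taxon)),
                   stringsAsFactors = FALSE)
  if (any(df$new == "*")) stop("new state may not be a wildcard")
  if (any(df$char < 1L)) stop("character indices are 1-based")
  class(df) <- c("recoding_ledger", "data.frame")
  df
}

#' Read a recoding ledger from a delimited text file
#'
#' The file is tab-separated with columns `taxon`, `char`, `old`, `new`,
#' `note`.  See [promyliobatis_recodings()] for the ledger shipped with
#' the package.
#'
#' @param file path to a TSV file
#' @return a [recoding_ledger()]
#' @export
read_recoding_ledger <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE, comment.char = "#",
                   colClasses = "character")
  need <- c("taxon", "char", "old", "new")
  if (!all(need %in% names(df)))
    stop("ledger file must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$note)) df$note <- ""
  recoding_ledger(df$taxon, as.integer(df$char), df$old, df$new, df$note)
}

#' The recoding ledger of the Promyliobatis reanalysis
#'
#' The documented edits applied to the inherited pelagic-stingray matrix
#' (Claeson et al. 2010 base, with later extensions) before the
#' Promyliobatis gazolai analysis: ch. 9 polymorphic for Aetomylaeus;
#' ch. 16 polymorphic for Myliobatis; ch. 27 changed 1 -> 2 for
#' Aetomylaeus and set to 1 for Weissobatis; ch. 30 set to 1 for
#' Rhinoptera and Mobula; chs. 50-52 polymorphic for Myliobatis and
#' Aetomylaeus and ch. 63 polymorphic for Myliobatis (tooth characters
#' with high intra-/interspecific variation); ch. 50 changed 1 -> 0 for
#' Rhinoptera.
#'
#' Entries whose published description omits the prior state carry a `"*"`
#' wildcard; the tooth-character polymorphisms whose member states are not
#' printed are recorded as `0/1` and flagged in the note column.  A
#' further set of published updates (chs. 52, 54, 55, 64, 65, after
#' Blanco) names no taxa and therefore cannot be represented as concrete
#' ledger entries.  The base matrix itself is not distributed with the
#' package; this ledger documents the edits and is replayable on any
#' matrix that uses the same taxon labels and character numbering.
#'
#' @return a [recoding_ledger()]
#' @export
promyliobatis_recodings <- function() {
  read_recoding_ledger(system.file("extdata", "promyliobatis_recodings.tsv",
                                   package = "maxpars", mustWork = TRUE))
}

parse_ledger_state <- function(s, max_state) {
  s <- trimws(s)
  if (s == "*") return(NULL)                     # wildcard
  if (s == "?") return(NA)                       # missing
  sort(unique(parse_cell_token(s)))
}

#' Apply a recoding ledger to a matrix
#'
#' Each entry replaces one cell.  An entry whose `old` state matches
#' neither the current cell nor the entry's `new` state raises a conflict
#' error naming the taxon, character, found and expected states.  Cells
#' already equal to `new` are left untouched, so re-applying a ledger is a
#' no-op (idempotence).  The per-cell changes actually made are attached
#' as attribute `"diff"` (a data frame).
#'
#' @param m a [char_matrix()]
#' @param ledger a [recoding_ledger()]
#' @return the recoded matrix, with a `"diff"` attribute
#' @examples
#' m <- char_matrix(rbind(Aetomylaeus = c("1", "0"), Rhinoptera = c("0", "1")))
#' led <- recoding_ledger("Aetomylaeus", 1, "1", "2", "example")
#' apply_recodings(m, led)
#' @export
apply_recodings <- function(m, ledger) {
  stopifnot(inherits(m, "char_matrix"), inherits(ledger, "recoding_ledger"))
  diff <- data.frame(taxon = character(0), char = integer(0),
                     from = character(0), to = character(0))
  for (k in seq_len(nrow(ledger))) {
    tx <- ledger$taxon[k]; ch <- ledger$char[k]
    i <- match(tx, m$taxa)
    if (is.na(i)) stop("recoding conflict: unknown taxon '", tx, "'")
    if (ch < 1L || ch > n_char(m))
      stop("recoding conflict: character ", ch, " out of range for '", tx, "'")
    ms <- m$specs$max_state[ch]
    new <- parse_ledger_state(ledger$new[k], ms)
    old <- parse_ledger_state(ledger$old[k], ms)
    cur_missing <- m$missing[i, ch]
    cur <- if (cur_missing) NA else bits_to_states(m$bits[i, ch])
    same <- function(a, b) {
      (length(a) == 1L && is.na(a[1]) && length(b) == 1L && is.na(b[1])) ||
        (!anyNA(a) && !anyNA(b) && length(a) == length(b) && all(a == b))
    }
    if (same(cur, new)) next                    # already applied
    if (!is.null(old) && !same(cur, old)) {
      stop("recoding conflict for taxon '", tx, "', ch. ", ch,
           ": found (", if (cur_missing) "?" else paste(cur, collapse = "/"),
           "), expected (", ledger$old[k], ")")
    }
    if (length(new) == 1L && is.na(new[1])) {
      m$missing[i, ch] <- TRUE; m$gap[i, ch] <- FALSE
    } else {
      if (max(new) > ms) {
        # recoding introduces a state above the observed range: widen spec
        m$specs$max_state[ch] <- max(new)
        full <- full_range_bits(max(new))
        m$bits[m$missing[, ch], ch] <- full
      }
      m$missing[i, ch] <- FALSE; m$gap[i, ch] <- FALSE
      m$bits[i, ch] <- states_to_bits(new)
    }
    diff <- rbind(diff, data.frame(
      taxon = tx, char = ch,
      from = if (cur_missing) "?" else paste(cur, collapse = "/"),
      to = ledger$new[k]))
  }
  m <- validate_char_matrix(m)
  attr(m, "diff") <- diff
  m
}
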
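# State-set utilities.  A cell is a set of admissible integer states stored
# as a bitmask (bit s set <=> state s admissible, 0 <= s <= 30).  A missing
# or inapplicable cell carries the full declared range of its character.

MAX_STATE <- 30L

states_to_bits <- function(states) {
  if (length(states) == 0L) return(0L)
  stopifnot(all(states >= 0L), all(states <= MAX_STATE))
  b <- 0L
  for (s in unique(as.integer(states))) b <- bitwOr(b, bitwShiftL(1L, s))
  b
}

bits_to_states <- function(bits) {
  which(bitwAnd(bits, bitwShiftL(1L, 0:MAX_STATE)) != 0L) - 1L
}

full_range_bits <- function(max_state) {
  # bits 0..max_state all set
  bitwShiftL(1L, max_state + 1L) - 1L
}

# Parse one matrix cell token into an integer state vector, or NA for
# missing/gap.  Accepts "0", "{0 1}", "{01}", "(01)", "[01]", "0/1".
parse_cell_token <- function(tok, missing_char = "?", gap_char = "-") {
  tok <- trimws(tok)
  if (tok == missing_char) return(structure(NA, kind = "missing"))
  if (tok == gap_char) return(structure(NA, kind = "gap"))
  inner <- sub("^[\\{\\(\\[]\\s*", "", tok, perl = TRUE)
  inner <- sub("\\s*[\\}\\)\\]]$", "", inner, perl = TRUE)
  parts <- strsplit(inner, "[[:space:]/,]+")[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 1L && nchar(parts) > 1L) {
    # compact polymorphism: "{01}" -> 0, 1
    parts <- strsplit(parts, "")[[1]]
  }
  if (!all(grepl("^[0-9]$", parts))) {
    stop("unparseable cell token: '", tok, "'", call. = FALSE)
  }
  sort(unique(as.integer(parts)))
}

format_cell_token <- function(states, is_missing, was_gap,
                              style = c("nexus", "tnt"),
                              missing_char = "?", gap_char = "-") {
  style <- match.arg(style)
  if (is_missing) return(if (was_gap) gap_char else missing_char)
  if (length(states) == 1L) return(as.character(states))
  if (style == "nexus") paste0("{", paste(states, collapse = " "), "}")
  else paste0("[", paste(states, collapse = ""), "]")
}

# Normalize a taxon label: strip quotes, collapse internal whitespace to "_".
normalize_label <- function(x) {
  x <- gsub("['\"]", "", x)
  x <- trimws(x)
  gsub("[[:space:]]+", "_", x)
}
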
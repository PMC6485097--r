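# Whole-matrix tree length via the compiled kernel, plus the ensemble
# homoplasy statistics CI and RI.

# Precompute kernel inputs from a char_matrix (rows in m$taxa order).
kernel_data <- function(m) {
  ntax <- n_taxa(m); nchar <- n_char(m)
  lo <- hi <- matrix(0L, ntax, nchar)
  for (j in seq_len(nchar)) {
    for (i in seq_len(ntax)) {
      s <- bits_to_states(m$bits[i, j])
      lo[i, j] <- min(s); hi[i, j] <- max(s)
    }
  }
  list(bits = m$bits, lo = lo, hi = hi,
       ordered = m$specs$ordered, weights = m$specs$weight)
}

# Length of a tree given as (edge matrix over node ids, root id) against
# prepped kernel data whose rows are indexed directly by tip id.
ed_length <- function(edge, root, dat) {
  C_pars_length(edge, root, dat$bits, dat$lo, dat$hi, dat$ordered,
                dat$weights)
}

# Convert an ape phylo whose tips are matrix taxa into kernel inputs:
# tip i of the phylo indexes data row match(tip.label[i], taxa).
phylo_kernel_data <- function(tree, m) {
  idx <- match(tree$tip.label, m$taxa)
  if (anyNA(idx))
    stop("tree leaves not in matrix: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  if (length(idx) != n_taxa(m))
    stop("matrix taxa not in tree: ",
         paste(setdiff(m$taxa, tree$tip.label), collapse = ", "))
  dat <- kernel_data(m)
  dat$bits <- dat$bits[idx, , drop = FALSE]
  dat$lo <- dat$lo[idx, , drop = FALSE]
  dat$hi <- dat$hi[idx, , drop = FALSE]
  dat
}

#' Parsimony length of a tree
#'
#' Total number of character-state changes ("steps") required by a matrix
#' on a fixed binary tree, dispatching each character to Fitch (unordered)
#' or Wagner (ordered) optimization according to its spec, and summing
#' with character weights.
#'
#' @param tree a binary tree of class `phylo` whose tip labels are exactly
#'   the matrix taxa
#' @param m a [char_matrix()]
#' @return a list of class `parsimony_fit`: `total_length`,
#'   `per_char_steps` (integer per character, unweighted), `tree`.
#' @examples
#' sim <- simulate_matrix(n_taxa = 6, n_char = 10, seed = 1)
#' tree_length(sim$tree, sim$matrix)
#' @export
tree_length <- function(tree, m) {
  stopifnot(inherits(tree, "phylo"), inherits(m, "char_matrix"))
  dat <- phylo_kernel_data(tree, m)
  ntip <- length(tree$tip.label)
  res <- C_pars_length(tree$edge, ntip + 1L, dat$bits, dat$lo, dat$hi,
                       dat$ordered, dat$weights)
  structure(list(total_length = res$total_length,
                 per_char_steps = res$per_char_steps,
                 tree = tree),
            class = "parsimony_fit")
}

#' @export
print.parsimony_fit <- function(x, ...) {
  cat("parsimony fit: length", x$total_length, "over",
      length(x$per_char_steps), "characters\n")
  invisible(x)
}

#' Ensemble homoplasy statistics (CI and RI)
#'
#' The consistency index CI = M/S and retention index RI = (G-S)/(G-M),
#' where S is the observed tree length, M the sum of per-character minimum
#' conceivable steps and G the sum of maximum conceivable (star-tree)
#' steps.  CI = 1 means the matrix fits the tree with no homoplasy.
#' Software traditions differ on whether parsimony-uninformative
#' characters enter the sums; both modes are provided.
#'
#' @param m a [char_matrix()]
#' @param tree a `phylo`, or a list of equally parsimonious trees (all
#'   share S; the first is used)
#' @param include_uninformative include parsimony-uninformative characters
#'   in M, S and G (default `TRUE`)
#' @return object of class `homoplasy_stats`: `M`, `S`, `G`, `CI`, `RI`,
#'   and a per-character table `per_char` (`char`, `steps`, `min_steps`,
#'   `max_steps`, `ci`, `ri`, `informative`).
#' @examples
#' sim <- simulate_matrix(n_taxa = 6, n_char = 10, seed = 1)
#' ensemble_stats(sim$matrix, sim$tree)
#' @export
ensemble_stats <- function(m, tree, include_uninformative = TRUE) {
  if (is.list(tree) && !inherits(tree, "phylo")) tree <- tree[[1]]
  fit <- tree_length(tree, m)
  s <- as.integer(fit$per_char_steps)
  mi <- gi <- integer(n_char(m))
  for (j in seq_len(n_char(m))) {
    col <- matrix_column(m, j)
    mi[j] <- min_steps(col, m$specs$ordered[j])
    gi[j] <- max_steps(col, m$specs$ordered[j])
  }
  info <- ifelse(is.na(gi), TRUE, gi > mi)
  ci <- ifelse(s > 0, mi / s, 1)
  ri <- ifelse(!is.na(gi) & gi > mi, (gi - s) / (gi - mi), NA_real_)
  keep <- if (include_uninformative) rep(TRUE, length(s)) else info
  w <- m$specs$weight
  M <- sum(w[keep] * mi[keep]); S <- sum(w[keep] * s[keep])
  G <- sum(w[keep] * gi[keep])
  CI <- if (S > 0) M / S else 1
  RI <- if (is.na(G)) {
    warning("RI unavailable: ordered characters with too many observed ",
            "cells for exact maximum-step enumeration")
    NA_real_
  } else if (G > M) (G - S) / (G - M) else {
    if (S > M) warning("RI undefined: G = M with S > M")
    NA_real_
  }
  structure(list(M = M, S = S, G = G, CI = CI, RI = RI,
                 include_uninformative = include_uninformative,
                 per_char = data.frame(char = seq_along(s), steps = s,
                                       min_steps = mi, max_steps = gi,
                                       ci = ci, ri = ri,
                                       informative = info)),
            class = "homoplasy_stats")
}

#' @export
print.homoplasy_stats <- function(x, ...) {
  cat(sprintf("tree length S = %g (M = %g, G = %g)%s\n", x$S, x$M, x$G,
              if (x$include_uninformative) "" else " [informative characters only]"))
  cat(sprintf("CI = %.2f  RI = %s\n", round(x$CI, 2),
              if (is.na(x$RI)) "undefined" else sprintf("%.2f", round(x$RI, 2))))
  invisible(x)
}

#' Per-character diagnostics table
#'
#' One row per character: observed steps on the tree, minimum and maximum
#' conceivable steps, per-character CI and RI, informativeness.  Suitable
#' for writing as TSV.
#'
#' @inheritParams ensemble_stats
#' @return a data frame
#' @export
character_diagnostics <- function(m, tree) {
  ensemble_stats(m, tree)$per_char
}
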
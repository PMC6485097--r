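# Per-character parsimony machinery.  fitch_steps()/wagner_steps() are
# plain-R, column-at-a-time implementations (they also expose the Fitch
# downpass sets); tree_length() batches all characters through the
# compiled kernel.  The two routes are cross-checked in the test suite.

# A "column" is a list of integer state vectors named by taxon (as from
# matrix_column()), with attributes `missing` (logical) and `max_state`.
as_column <- function(column, labels) {
  if (is.null(names(column))) {
    stopifnot(length(column) == length(labels))
    names(column) <- labels
  }
  miss <- attr(column, "missing")
  if (is.null(miss)) miss <- vapply(column, function(s) anyNA(s) || length(s) == 0L, logical(1))
  ms <- attr(column, "max_state")
  if (is.null(ms)) {
    obs <- unlist(column[!miss])
    ms <- if (length(obs)) max(obs) else 1L
  }
  sets <- lapply(seq_along(column), function(i) {
    if (miss[i]) 0:ms else as.integer(column[[i]])
  })
  names(sets) <- names(column)
  attr(sets, "missing") <- miss
  attr(sets, "max_state") <- ms
  sets
}

#' Fitch (unordered) parsimony steps of one character on a tree
#'
#' Computes the minimum number of state changes needed to explain a single
#' unordered character on a fixed binary tree, by Fitch state-set folding.
#' Missing cells span the full state range and are free.  The downpass
#' state sets are attached as attribute `"downpass"` (indexed by node
#' number of the postorder-reordered tree).
#'
#' @param tree an unrooted (or rooted) binary tree of class `phylo`
#' @param column a list of integer state vectors, named by taxon or in
#'   `tree$tip.label` order; `NA`/empty entries are missing.  Columns from
#'   [matrix_column()] work directly.
#' @return integer step count, with attribute `"downpass"`
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_steps(tr, list(A = 0, B = 0, C = 1, D = 1))
#' @export
fitch_steps <- function(tree, column) {
  sets <- as_column(column, tree$tip.label)
  idx <- match(tree$tip.label, names(sets))
  if (anyNA(idx))
    stop("no column entry for leaf: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(tree$edge)
  node_sets <- vector("list", nnode)
  for (i in seq_along(idx)) node_sets[[i]] <- sets[[idx[i]]]
  steps <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    a <- node_sets[[p]]; b <- node_sets[[ch]]
    if (is.null(a)) node_sets[[p]] <- b
    else {
      inter <- intersect(a, b)
      if (length(inter)) node_sets[[p]] <- inter
      else { node_sets[[p]] <- union(a, b); steps <- steps + 1L }
    }
  }
  structure(steps, downpass = node_sets)
}

#' Wagner (ordered) parsimony steps of one character on a tree
#'
#' As [fitch_steps()] but for linearly ordered states with cost
#' `|i - j|`, by Farris interval folding.  Polymorphic cells contribute
#' the interval `[min, max]` of their member set; missing cells the full
#' range.
#'
#' @inheritParams fitch_steps
#' @return integer step count
#' @export
wagner_steps <- function(tree, column) {
  sets <- as_column(column, tree$tip.label)
  idx <- match(tree$tip.label, names(sets))
  if (anyNA(idx))
    stop("no column entry for leaf: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(tree$edge)
  lo <- rep(NA_integer_, nnode); hi <- rep(NA_integer_, nnode)
  for (i in seq_along(idx)) {
    lo[i] <- min(sets[[idx[i]]]); hi[i] <- max(sets[[idx[i]]])
  }
  steps <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (is.na(lo[p])) { lo[p] <- lo[ch]; hi[p] <- hi[ch] }
    else {
      ilo <- max(lo[p], lo[ch]); ihi <- min(hi[p], hi[ch])
      if (ilo <= ihi) { lo[p] <- ilo; hi[p] <- ihi }
      else {
        steps <- steps + (ilo - ihi)
        nlo <- min(hi[p], hi[ch]); nhi <- max(lo[p], lo[ch])
        lo[p] <- nlo; hi[p] <- nhi
      }
    }
  }
  steps
}

#' Minimum conceivable steps of a character
#'
#' The smallest number of changes the character can require on any tree:
#' for unordered characters, (size of the smallest state set hitting every
#' cell's admissible set) - 1, minimized over polymorphic resolutions; for
#' ordered characters, the forced range `max(lo) - min(hi)` (0 if the cell
#' intervals share a point).  Missing cells are ignored.
#'
#' @param column as in [fitch_steps()] (taxon names not required)
#' @param ordered treat the character as ordered?
#' @return integer
#' @export
min_steps <- function(column, ordered = FALSE) {
  sets <- as_column(column, paste0("t", seq_along(column)))
  miss <- attr(sets, "missing")
  obs <- sets[!miss]
  if (!length(obs)) return(0L)
  if (ordered) {
    lo <- vapply(obs, min, integer(1)); hi <- vapply(obs, max, integer(1))
    return(max(0L, max(lo) - min(hi)))
  }
  pool <- sort(unique(unlist(obs)))
  if (length(pool) == 1L) return(0L)
  for (k in seq_along(pool)) {
    hit <- combn(pool, k, function(sub) {
      all(vapply(obs, function(s) any(s %in% sub), logical(1)))
    })
    if (any(hit)) return(k - 1L)
  }
  length(pool) - 1L
}

#' Maximum conceivable steps of a character
#'
#' The largest number of changes the character can require on any binary
#' tree: for unordered characters this is attained on the star tree and
#' equals `n_eff - max_s #{cells admitting s}`, where `n_eff` counts
#' non-missing cells.  No closed form is exact for ordered characters
#' (internal nodes can absorb part of the range), so the maximum is
#' found by explicit enumeration over all topologies when at most 8
#' cells are non-missing, and reported as `NA` beyond that.
#'
#' @inheritParams min_steps
#' @return integer (`NA` for ordered characters with more than 8
#'   observed cells)
#' @export
max_steps <- function(column, ordered = FALSE) {
  sets <- as_column(column, paste0("t", seq_along(column)))
  miss <- attr(sets, "missing")
  obs <- sets[!miss]
  if (length(obs) <= 1L) return(0L)
  if (!ordered) {
    pool <- sort(unique(unlist(obs)))
    best <- max(vapply(pool, function(s) {
      sum(vapply(obs, function(x) s %in% x, logical(1)))
    }, integer(1)))
    return(length(obs) - best)
  }
  n <- length(obs)
  if (n == 2L) {
    # two cells: worst (= only) tree joins them directly
    gap <- max(0L, max(min(obs[[1]]), min(obs[[2]])) -
                 min(max(obs[[1]]), max(obs[[2]])))
    return(gap)
  }
  if (n > 8L) return(NA_integer_)
  lo <- matrix(vapply(obs, min, integer(1)), n, 1)
  hi <- matrix(vapply(obs, max, integer(1)), n, 1)
  dat <- list(bits = matrix(1L, n, 1), lo = lo, hi = hi,
              ordered = TRUE, weights = 1)
  worst <- 0L
  walk_topologies(n, function(ed) {
    len <- ed_length(ed$edge, ed$root, dat)$total_length
    if (len > worst) worst <<- as.integer(len)
  })
  worst
}

# Is the character parsimony-informative?  Uninformative characters have
# identical length on every tree, i.e. min == max conceivable steps.
is_informative <- function(column, ordered = FALSE) {
  max_steps(column, ordered) > min_steps(column, ordered)
}
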
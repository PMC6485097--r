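# Ancestral state machinery: a Sankoff-style dynamic program over small
# state spaces.  Independent of the compiled Fitch/Wagner kernel (the two
# agree on binary trees; the DP additionally handles multifurcations,
# which the zero-length-branch collapse rule needs).

# per-character transition cost
step_cost <- function(s, t, ordered) if (ordered) abs(s - t) else as.numeric(s != t)

# DP tables for one tree (phylo, rooted or not) against a matrix.
# Returns list(per_char cost matrices [node x state], postorder tree).
sankoff_tables <- function(tree, m) {
  idx <- match(tree$tip.label, m$taxa)
  if (anyNA(idx))
    stop("tree leaves not in matrix: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode_all <- max(tree$edge)
  tabs <- vector("list", n_char(m))
  for (j in seq_len(n_char(m))) {
    k <- m$specs$max_state[j]
    states <- 0:k
    ordered <- m$specs$ordered[j]
    cost <- matrix(0, nnode_all, k + 1L)
    for (i in seq_len(ntip)) {
      adm <- bits_to_states(m$bits[idx[i], j])
      cost[i, ] <- ifelse(states %in% adm, 0, Inf)
    }
    dmat <- outer(states, states, function(a, b) {
      if (ordered) abs(a - b) else (a != b) + 0
    })
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      # cost[p, s] += min_t cost[v, t] + d(s, t)
      add <- apply(dmat, 1, function(drow) min(cost[v, ] + drow))
      cost[p, ] <- cost[p, ] + add
    }
    tabs[[j]] <- cost
  }
  list(cost = tabs, tree = tree, ntip = ntip)
}

# tree length by the DP (handles polytomies); root = ntip+1 convention
sankoff_length <- function(tree, m) {
  st <- sankoff_tables(tree, m)
  root <- st$ntip + 1L
  per <- vapply(seq_len(n_char(m)), function(j) min(st$cost[[j]][root, ]),
                numeric(1))
  list(per_char_steps = per, total_length = sum(m$specs$weight * per))
}

#' Root a tree on a designated outgroup taxon
#'
#' Ancestral-state polarity requires a rooted tree; published analyses
#' root the displayed tree on an outgroup.
#'
#' @param tree a `phylo`
#' @param outgroup a tip label
#' @return a rooted binary `phylo`
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# Traceback of one reconstruction.  method: acctran prefers a change on
# the current edge when total cost ties (changes pulled rootward);
# deltran prefers keeping the parent state (changes pushed tipward).
# Returns node x char integer state matrix.
sankoff_traceback <- function(st, m, method = c("acctran", "deltran")) {
  method <- match.arg(method)
  tree <- st$tree
  ntip <- st$ntip
  root <- ntip + 1L
  nnode_all <- max(tree$edge)
  assign_mat <- matrix(NA_integer_, nnode_all, n_char(m))
  # preorder = reverse postorder edge sweep
  for (j in seq_len(n_char(m))) {
    cost <- st$cost[[j]]
    k <- m$specs$max_state[j]
    states <- 0:k
    ordered <- m$specs$ordered[j]
    rc <- cost[root, ]
    assign_mat[root, j] <- states[which(rc == min(rc))][1]
    for (e in rev(seq_len(nrow(tree$edge)))) {
      p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      a <- assign_mat[p, j]
      tot <- cost[v, ] + vapply(states, step_cost, numeric(1), t = a,
                                ordered = ordered)
      cand <- states[tot == min(tot)]
      assign_mat[v, j] <- if (method == "deltran") {
        if (a %in% cand) a else cand[1]
      } else {
        if (length(cand) > 1L && a %in% cand) setdiff(cand, a)[1] else cand[1]
      }
    }
  }
  assign_mat
}

#' Ancestral character states by parsimony
#'
#' Reconstructs one state per node per character on a rooted tree, using
#' a minimum-change (Sankoff) traceback with ACCTRAN (changes placed as
#' close to the root as possible) or DELTRAN (delayed) tie-breaking.  The
#' total number of implied changes per character always equals its
#' parsimony step count.
#'
#' @param tree a rooted binary `phylo` (see [root_on_outgroup()])
#' @param m a [char_matrix()]
#' @param method `"acctran"` (default) or `"deltran"`
#' @return integer matrix (nodes x characters) of reconstructed states;
#'   rows follow the postorder-reordered tree's node numbering, returned
#'   as attribute `"tree"`
#' @export
acctran_states <- function(tree, m, method = "acctran") {
  if (!ape::is.rooted(tree))
    stop("tree must be rooted; root it on an outgroup first, e.g. ",
         "root_on_outgroup(tree, tree$tip.label[1])")
  st <- sankoff_tables(tree, m)
  out <- sankoff_traceback(st, m, method)
  attr(out, "tree") <- st$tree
  out
}

#' Collapse internal branches of minimum length zero
#'
#' A branch is collapsed when contracting it does not change the tree
#' length, i.e. when some most-parsimonious reconstruction places no
#' change on it.  This is the collapse rule under which a search's
#' "number of distinct trees" is conventionally reported.
#'
#' @param tree a `phylo` over the matrix taxa
#' @param m a [char_matrix()]
#' @return a (possibly multifurcating) `phylo`
#' @export
collapse_zero_branches <- function(tree, m) {
  taxa <- sort(tree$tip.label)
  base_len <- sankoff_length(tree, m)$total_length
  sides <- phylo_splits(tree, taxa)
  keep <- vapply(sides, function(side) {
    pruned <- clades_to_phylo(sides[!vapply(sides, identical, logical(1), side)],
                              taxa)
    sankoff_length(pruned, m)$total_length > base_len
  }, logical(1))
  clades_to_phylo(sides[keep], taxa)
}
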
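# Independent oracles for the parsimony machinery.  Deliberately naive:
# exhaustive minimization over every ancestral state assignment, and
# topology enumeration borrowed from phangorn (not from the package's own
# enumerator), so the fast implementations are checked against code that
# shares nothing with them.

# Brute-force step count of one character on a tree.  `column` is a list
# of admissible state vectors per tip (NA = missing); internal nodes take
# every state in 0:max_state; leaf cost is minimized over the leaf's
# admissible set given its parent's state.
bf_steps <- function(tree, column, ordered = FALSE, max_state = NULL) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  if (!is.null(names(column))) column <- column[tree$tip.label]
  sets <- lapply(column, function(s) if (anyNA(s)) NULL else as.integer(s))
  if (is.null(max_state))
    max_state <- max(1L, unlist(sets))
  for (i in seq_along(sets)) if (is.null(sets[[i]])) sets[[i]] <- 0:max_state
  # ordered model: a polymorphic leaf is the interval [min, max]
  if (ordered) sets <- lapply(sets, function(s) min(s):max(s))
  ints <- sort(unique(tree$edge[tree$edge > n]))
  states <- 0:max_state
  d <- function(a, b) if (ordered) abs(a - b) else as.numeric(a != b)
  grid <- expand.grid(rep(list(states), length(ints)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    asg <- integer(max(tree$edge))
    asg[ints] <- as.integer(grid[g, ])
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      cost <- cost + if (v <= n) min(d(asg[p], sets[[v]]))
                     else d(asg[p], asg[v])
    }
    best <- min(best, cost)
  }
  best
}

# every unrooted binary topology, via phangorn (independent enumeration).
# expanded to a plain list: compressed multiPhylo elements lack tip
# labels when iterated directly
all_topologies <- function(labels) {
  trees <- phangorn::allTrees(length(labels), rooted = FALSE,
                              tip.label = labels)
  lapply(seq_along(trees), function(i) trees[[i]])
}

# brute-force matrix length on a tree
bf_length <- function(tree, m) {
  sum(vapply(seq_len(n_char(m)), function(j) {
    col <- matrix_column(m, j)
    col2 <- lapply(seq_along(col), function(i) {
      if (attr(col, "missing")[i]) NA else col[[i]]
    })
    names(col2) <- names(col)
    m$specs$weight[j] * bf_steps(tree, col2[tree$tip.label],
                                 ordered = m$specs$ordered[j],
                                 max_state = m$specs$max_state[j])
  }, numeric(1)))
}

topo_key <- function(tree, taxa) maxpars:::phylo_topology_key(tree, taxa)

split_keys <- function(tree, taxa) {
  vapply(maxpars:::phylo_splits(tree, taxa), maxpars:::split_key, character(1))
}

# a small fixed homoplasy-free 8-taxon matrix built on a known tree
perfect_fixture <- function(n_taxa = 8L, n_char = 14L, seed = 42L) {
  tr <- maxpars:::with_seed(seed,
    ape::rtopology(n_taxa, rooted = FALSE,
                   tip.label = paste0("t", seq_len(n_taxa))))
  congruent_matrix(tr, n_char, seed = seed)
}
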
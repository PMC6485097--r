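# Consensus trees summarized from bipartition tallies.  Splits are
# canonicalized as the side not containing the reference taxon (the
# lexicographically first label), tallied across trees, and the retained
# (automatically compatible) splits are reassembled into a tree.

# tally of split keys across a list of phylo trees with a common leaf set
split_tally <- function(trees, taxa) {
  counts <- new.env(parent = emptyenv())
  sides <- list()
  for (tr in trees) {
    if (!setequal(tr$tip.label, taxa))
      stop("trees have mismatched leaf sets")
    for (side in phylo_splits(tr, taxa)) {
      key <- split_key(side)
      if (is.null(counts[[key]])) {
        counts[[key]] <- 1L
        sides[[key]] <- side
      } else counts[[key]] <- counts[[key]] + 1L
    }
  }
  keys <- ls(counts)
  data_sides <- sides[keys]
  list(keys = keys, sides = data_sides,
       counts = vapply(keys, function(k) counts[[k]], integer(1)))
}

#' Strict consensus tree
#'
#' The (possibly multifurcating) tree whose internal branches are exactly
#' the bipartitions shared by every input tree.
#'
#' @param trees a list of `phylo` trees over the same leaf set (or an
#'   `mp_search` result)
#' @return a `phylo` tree
#' @examples
#' trees <- list(ape::read.tree(text = "((A,B),(C,D),E);"),
#'               ape::read.tree(text = "((A,B),C,(D,E));"))
#' strict_consensus(trees)
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "mp_search")) trees <- trees$trees
  stopifnot(length(trees) >= 1L)
  taxa <- sort(trees[[1]]$tip.label)
  tl <- split_tally(trees, taxa)
  keep <- tl$counts == length(trees)
  clades_to_phylo(tl$sides[keep], taxa)
}

#' Majority-rule consensus tree
#'
#' Retains every bipartition occurring in more than `threshold` of the
#' input trees; the observed frequencies (percent) are attached as node
#' labels and as attribute `"frequencies"`.
#'
#' @inheritParams strict_consensus
#' @param threshold minimum frequency (0.5 to 1]; 1 reproduces the strict
#'   consensus
#' @return a `phylo` tree with node labels giving percentages
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "mp_search")) trees <- trees$trees
  stopifnot(length(trees) >= 1L, threshold >= 0.5, threshold <= 1)
  taxa <- sort(trees[[1]]$tip.label)
  tl <- split_tally(trees, taxa)
  freq <- tl$counts / length(trees)
  keep <- if (threshold == 1) freq >= 1 else freq > threshold
  pct <- round(100 * freq[keep], 1)
  tree <- clades_to_phylo(tl$sides[keep], taxa, labels = pct)
  attr(tree, "frequencies") <- data.frame(
    clade = vapply(tl$sides[keep], function(s) paste(taxa[s], collapse = " "),
                   character(1)),
    frequency = pct)
  tree
}
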
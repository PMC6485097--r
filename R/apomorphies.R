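# Synapomorphy mapping: per-branch character-state changes implied by the
# ancestral reconstructions, with per-character consistency indices.

#' Per-character consistency index on a tree
#'
#' `ci = min_steps / observed_steps` for each character (1 when a
#' character needs no steps).  This is the per-character CI printed next
#' to synapomorphies in published character lists.
#'
#' @param m a [char_matrix()]
#' @param tree a `phylo` over the matrix taxa
#' @return a data frame: `char`, `steps`, `min_steps`, `ci`
#' @export
per_character_ci <- function(m, tree) {
  fit <- tree_length(tree, m)
  s <- as.integer(fit$per_char_steps)
  mi <- vapply(seq_len(n_char(m)), function(j) {
    min_steps(matrix_column(m, j), m$specs$ordered[j])
  }, integer(1))
  data.frame(char = seq_len(n_char(m)), steps = s, min_steps = mi,
             ci = ifelse(s > 0, mi / s, 1))
}

# list the state changes of one reconstruction: data.frame(edge, node,
# char, from, to)
reconstruction_changes <- function(states, tree) {
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    ch <- which(states[p, ] != states[v, ])
    if (length(ch))
      out[[length(out) + 1L]] <- data.frame(
        edge = e, node = v, char = ch,
        from = states[p, ch], to = states[v, ch])
  }
  if (!length(out))
    return(data.frame(edge = integer(0), node = integer(0), char = integer(0),
                      from = integer(0), to = integer(0)))
  do.call(rbind, out)
}

#' Map synapomorphies onto the branches of a tree
#'
#' Lists every character-state change implied by the ACCTRAN
#' reconstruction, branch by branch, flags the changes that are also
#' present (same branch, same states) under DELTRAN as `unambiguous`,
#' and joins the per-character CI.  Branches are addressed by the set of
#' tips descending from them.
#'
#' @param tree a `phylo` over the matrix taxa; rooted, or rootable via
#'   `outgroup`
#' @param m a [char_matrix()]
#' @param outgroup tip label to root on when `tree` is unrooted; defaults
#'   to the first matrix taxon (with a warning, since the choice sets
#'   character polarity)
#' @return a data frame of class `apomorphy_list`: `branch` (space-
#'   separated tip labels of the clade, or the tip name for terminal
#'   branches), `char` (1-based), `from`, `to`, `unambiguous`, `ci`
#' @examples
#' sim <- simulate_matrix(n_taxa = 6, n_char = 12, seed = 2)
#' synapomorphy_map(sim$tree, sim$matrix, outgroup = "t1")
#' @export
synapomorphy_map <- function(tree, m, outgroup = NULL) {
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup)) {
      outgroup <- m$taxa[1]
      warning("no outgroup given; rooting on first matrix taxon '",
              outgroup, "'")
    }
    tree <- root_on_outgroup(tree, outgroup)
  }
  st <- sankoff_tables(tree, m)
  acc <- sankoff_traceback(st, m, "acctran")
  del <- sankoff_traceback(st, m, "deltran")
  ptree <- st$tree
  ntip <- st$ntip

  ch_acc <- reconstruction_changes(acc, ptree)
  ch_del <- reconstruction_changes(del, ptree)
  key <- function(d) paste(d$node, d$char, d$from, d$to)
  unamb <- key(ch_acc) %in% key(ch_del)

  # branch address: tips below the child node
  tipsets <- node_tipsets(ptree)
  cis <- per_character_ci(m, tree)
  out <- data.frame(
    branch = vapply(ch_acc$node, function(v) {
      paste(sort(ptree$tip.label[tipsets[[v]]]), collapse = " ")
    }, character(1)),
    char = ch_acc$char,
    from = ch_acc$from,
    to = ch_acc$to,
    unambiguous = unamb,
    ci = cis$ci[ch_acc$char]
  )
  out <- out[order(out$branch, out$char), ]
  rownames(out) <- NULL
  class(out) <- c("apomorphy_list", "data.frame")
  attr(out, "tree") <- ptree
  attr(out, "deltran") <- ch_del
  out
}

# tip indices below each node of a postorder phylo
node_tipsets <- function(tree) {
  nnode_all <- max(tree$edge)
  ntip <- length(tree$tip.label)
  sets <- vector("list", nnode_all)
  for (i in seq_len(ntip)) sets[[i]] <- i
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    sets[[p]] <- sort(unique(c(sets[[p]], sets[[v]])))
  }
  sets
}

#' @export
print.apomorphy_list <- function(x, ...) {
  cat("synapomorphy map:", nrow(x), "changes on",
      length(unique(x$branch)), "branches\n")
  print(as.data.frame(x))
  invisible(x)
}
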
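# Internal light-weight tree representation used by the searches.
#
# A tree is a list(edge, root): `edge` is a 2-column integer matrix of
# branches in arbitrary orientation over node ids, `root` an internal
# node id of degree 2-3.  Terminal ids are global taxon indices
# (1..n_taxa of the matrix, not necessarily all present in partial
# trees); internal ids live above n_taxa.  The compiled kernel orients
# trees itself, so rearrangements only edit `edge`.

ed_tree <- function(edge, root) list(edge = edge, root = root)

# the unique unrooted topology on three taxa
ed_init3 <- function(t1, t2, t3, internal_id) {
  ed_tree(matrix(c(internal_id, t1, internal_id, t2, internal_id, t3),
                 ncol = 2, byrow = TRUE), internal_id)
}

# insert `tip` on edge row k, creating internal node `w`
ed_insert <- function(ed, k, tip, w) {
  u <- ed$edge[k, 1]; v <- ed$edge[k, 2]
  ed$edge[k, ] <- c(u, w)
  ed$edge <- rbind(ed$edge, c(w, v), c(w, tip))
  ed
}

# adjacency + orientation away from root
ed_orient <- function(edge, root) {
  maxid <- max(edge[1], root, max(edge))
  adj <- vector("list", maxid)
  for (k in seq_len(nrow(edge))) {
    a <- edge[k, 1]; b <- edge[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- integer(maxid)
  parent[root] <- -1L
  stack <- root
  pre <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    for (u in adj[[v]]) if (u != parent[v]) {
      parent[u] <- v
      stack <- c(stack, u)
    }
  }
  list(pre = pre, post = rev(pre), parent = parent, adj = adj)
}

# tip ids present in the tree
ed_tips <- function(ed, ntip) {
  ids <- unique(as.vector(ed$edge))
  sort(ids[ids <= ntip])
}

# Non-trivial bipartitions as canonical keys.  Each split is represented
# by the side NOT containing the smallest present tip, sorted.
ed_splits <- function(ed, ntip) {
  o <- ed_orient(ed$edge, ed$root)
  tips <- ed_tips(ed, ntip)
  ref <- min(tips)
  npres <- length(tips)
  maxid <- length(o$parent)
  below <- vector("list", maxid)
  out <- list()
  for (v in o$post) {
    if (v <= ntip) below[[v]] <- v
    else {
      kids <- o$adj[[v]][o$adj[[v]] != o$parent[v]]
      below[[v]] <- sort(unlist(below[kids]))
    }
  }
  for (v in o$pre) {
    if (v <= ntip || identical(o$parent[v], -1L)) next
    side <- below[[v]]
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2L && length(side) <= npres - 2L)
      out[[length(out) + 1L]] <- side
  }
  unique(out)
}

split_key <- function(side) paste(side, collapse = ",")

# canonical topology identity (bipartition-set equality)
ed_topology_key <- function(ed, ntip) {
  keys <- sort(vapply(ed_splits(ed, ntip), split_key, character(1)))
  paste(keys, collapse = ";")
}

phylo_topology_key <- function(tree, taxa) {
  ed <- phylo_to_ed(tree, taxa)
  ed_topology_key(ed, length(taxa))
}

# Newick serialization of an ed tree (labels pre-normalized, no quoting
# needed); internal node labels optional via `node_label(v)`.
ed_newick <- function(ed, labels, ntip) {
  o <- ed_orient(ed$edge, ed$root)
  build <- function(v, from) {
    kids <- o$adj[[v]]
    kids <- kids[kids != from]
    if (v <= ntip && !length(kids)) return(labels[v])
    inner <- paste(vapply(kids, build, character(1), from = v), collapse = ",")
    if (v <= ntip) paste0("(", inner, ",", labels[v], ")") else paste0("(", inner, ")")
  }
  paste0(build(ed$root, 0L), ";")
}

ed_to_phylo <- function(ed, taxa) {
  ape::read.tree(text = ed_newick(ed, taxa, length(taxa)))
}

phylo_to_ed <- function(tree, taxa) {
  ntip <- length(tree$tip.label)
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx))
    stop("tree leaves not matrix taxa: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  n <- length(taxa)
  remap <- function(v) ifelse(v <= ntip, idx[v], n + (v - ntip))
  edge <- cbind(remap(tree$edge[, 1]), remap(tree$edge[, 2]))
  ed_tree(edge, n + 1L)
}

phylo_splits <- function(tree, taxa) {
  ed_splits(phylo_to_ed(tree, taxa), length(taxa))
}

# Does `tree` (ed form) contain bipartition `side` (tip ids)?  Checked via
# a synthetic binary character: the split is a branch of the tree iff the
# character needs exactly one step.
ed_has_split_dat <- function(side, ntip) {
  bits <- matrix(1L, ntip, 1L)
  bits[side, 1L] <- 2L
  list(bits = bits, lo = matrix(0L, ntip, 1L), hi = matrix(0L, ntip, 1L),
       ordered = FALSE, weights = 1)
}

ed_has_split <- function(ed, split_dat) {
  res <- C_pars_length(ed$edge, ed$root, split_dat$bits, split_dat$lo,
                       split_dat$hi, split_dat$ordered, split_dat$weights)
  res$total_length == 1
}

# Build a (possibly multifurcating) phylo from a laminar family of
# clades, each a set of tip ids excluding the reference taxon; optional
# per-clade labels (e.g. bootstrap percentages) become node labels.
clades_to_phylo <- function(clades, taxa, labels = NULL) {
  n <- length(taxa)
  ord <- order(-lengths(clades))
  clades <- clades[ord]
  labels <- if (!is.null(labels)) labels[ord]
  build <- function(members, active) {
    # active: indices into clades that are subsets of `members`
    tops <- active[vapply(active, function(i) {
      !any(vapply(active, function(j) {
        j != i && all(clades[[i]] %in% clades[[j]]) &&
          length(clades[[j]]) > length(clades[[i]])
      }, logical(1)))
    }, logical(1))]
    used <- unique(unlist(clades[tops]))
    parts <- character(0)
    for (i in tops) {
      sub <- active[vapply(active, function(j) {
        j != i && all(clades[[j]] %in% clades[[i]])
      }, logical(1))]
      inner <- build(clades[[i]], sub)
      lab <- if (!is.null(labels) && !is.na(labels[i])) labels[i] else ""
      parts <- c(parts, paste0(inner, lab))
    }
    loose <- setdiff(members, used)
    parts <- c(parts, taxa[loose])
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(build(seq_len(n), seq_along(clades)), ";")
  ape::read.tree(text = txt)
}
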
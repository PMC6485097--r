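# Heuristic parsimony search: random addition sequences (RAS) followed by
# tree-bisection-reconnection (TBR) branch swapping with first-improvement
# acceptance, then a plateau sweep that collects every equally
# parsimonious tree TBR-connected to the best trees found.

# --- TBR neighborhoods -------------------------------------------------

# Bisect the tree at edge row k and return the two parts with their
# degree-2 remnant vertices suppressed.  Each part is a list(edges,
# freed): `edges` a 2-column matrix (possibly 0 rows for a lone tip, in
# which case `tip` holds the vertex), `freed` the suppressed internal id
# (NA if the endpoint was a tip).
bisect_edge <- function(edge, k, ntip) {
  x <- edge[k, 1]; y <- edge[k, 2]
  rest <- edge[-k, , drop = FALSE]
  # vertices reachable from x in rest
  reach <- function(start) {
    seen <- start
    repeat {
      hit <- rest[, 1] %in% seen | rest[, 2] %in% seen
      new <- unique(c(rest[hit, 1], rest[hit, 2]))
      if (all(new %in% seen)) break
      seen <- unique(c(seen, new))
    }
    seen
  }
  side <- function(v) {
    if (v <= ntip) return(list(edges = rest[0, , drop = FALSE], tip = v, freed = NA_integer_))
    vs <- reach(v)
    e <- rest[rest[, 1] %in% vs & rest[, 2] %in% vs, , drop = FALSE]
    # v is now degree 2: suppress it
    at <- which(e[, 1] == v | e[, 2] == v)
    nb <- ifelse(e[at, 1] == v, e[at, 2], e[at, 1])
    stopifnot(length(at) == 2L)
    e <- e[-at, , drop = FALSE]
    if (length(nb) == 2L) e <- rbind(e, nb)
    list(edges = e, tip = NA_integer_, freed = v,
         merged = nrow(e))  # index of the merged edge (last row)
  }
  vx <- if (x <= ntip) x else NULL
  px <- side(x); py <- side(y)
  list(x = px, y = py)
}

# Apply `fun(edge2, root2)` to every TBR reconnection of a bisection;
# fun returning TRUE short-circuits the sweep (first improvement).
# Returns TRUE if short-circuited.
tbr_reconnect_sweep <- function(part_a, part_b, fun) {
  attach_points <- function(p) {
    if (!is.na(p$tip)) list(list(kind = "tip", v = p$tip))
    else lapply(seq_len(nrow(p$edges)), function(i) list(kind = "edge", i = i))
  }
  pa <- attach_points(part_a); pb <- attach_points(part_b)
  for (a in pa) {
    for (b in pb) {
      # skip the reconnection that recreates the original tree
      if (a$kind == "edge" && b$kind == "edge" &&
          !is.null(part_a$merged) && !is.null(part_b$merged) &&
          a$i == part_a$merged && b$i == part_b$merged) next
      ea <- part_a$edges; eb <- part_b$edges
      if (a$kind == "tip" && b$kind == "tip") next  # n = 2, impossible
      if (a$kind == "tip") {
        w2 <- part_b$freed
        bb <- eb[b$i, ]
        eb <- eb[-b$i, , drop = FALSE]
        edge2 <- rbind(ea, eb, c(w2, bb[1]), c(w2, bb[2]), c(w2, a$v))
        root2 <- w2
      } else if (b$kind == "tip") {
        w1 <- part_a$freed
        aa <- ea[a$i, ]
        ea <- ea[-a$i, , drop = FALSE]
        edge2 <- rbind(ea, eb, c(w1, aa[1]), c(w1, aa[2]), c(w1, b$v))
        root2 <- w1
      } else {
        w1 <- part_a$freed; w2 <- part_b$freed
        aa <- ea[a$i, ]; bb <- eb[b$i, ]
        ea <- ea[-a$i, , drop = FALSE]; eb <- eb[-b$i, , drop = FALSE]
        edge2 <- rbind(ea, eb, c(w1, aa[1]), c(w1, aa[2]),
                       c(w2, bb[1]), c(w2, bb[2]), c(w1, w2))
        root2 <- w1
      }
      if (isTRUE(fun(edge2, root2))) return(TRUE)
    }
  }
  FALSE
}

# visit TBR neighbors in canonical order; fun(edge2, root2) -> TRUE stops
tbr_sweep <- function(ed, ntip, fun) {
  for (k in seq_len(nrow(ed$edge))) {
    parts <- bisect_edge(ed$edge, k, ntip)
    if (!is.na(parts$x$tip) && !is.na(parts$y$tip)) next
    if (tbr_reconnect_sweep(parts$x, parts$y, fun)) return(TRUE)
  }
  FALSE
}

# First-improvement TBR descent to a local optimum (compiled sweep).
# An optional constraint bipartition (tip ids of one side) makes any
# tree containing that split cost `penalty` extra — the converse-
# constraint device of the Bremer searches.
tbr_descend <- function(ed, dat, ntip, constraint = NULL, penalty = 1e9) {
  cons <- integer(0)
  if (!is.null(constraint)) {
    cons <- rep(1L, ntip)
    cons[constraint] <- 2L
  }
  res <- C_tbr_descend(ed$edge, ed$root, dat$bits, dat$lo, dat$hi,
                       dat$ordered, dat$weights, cons, penalty)
  list(ed = ed_tree(res$edge, res$root), length = res$length)
}

# insertion lengths of `tip` on every branch, via the compiled scorer
insertion_lengths <- function(ed, tip, w, dat) {
  C_insertion_lengths(ed$edge, ed$root, tip, w, dat$bits, dat$lo, dat$hi,
                      dat$ordered, dat$weights)
}

# Collect every tree of the given length TBR-connected to the seeds
# (plateau closure), up to max_trees.
tbr_plateau <- function(seed_eds, target_len, dat, ntip, max_trees,
                        objective = NULL) {
  score <- function(edge, root) {
    if (is.null(objective)) ed_length(edge, root, dat)$total_length
    else objective(edge, root)
  }
  pool <- list()
  keys <- character(0)
  queue <- list()
  best <- target_len
  push <- function(ed) {
    key <- ed_topology_key(ed, ntip)
    if (!(key %in% keys)) {
      keys <<- c(keys, key)
      pool[[length(pool) + 1L]] <<- ed
      queue[[length(queue) + 1L]] <<- ed
    }
  }
  for (ed in seed_eds) push(ed)
  while (length(queue) && length(pool) <= max_trees) {
    ed <- queue[[1]]
    queue <- queue[-1]
    improved <- tbr_sweep(ed, ntip, function(edge2, root2) {
      l2 <- score(edge2, root2)
      if (l2 < best) {
        # plateau restart at the better level
        best <<- l2
        pool <<- list(); keys <<- character(0); queue <<- list()
        push(ed_tree(edge2, root2))
        return(TRUE)
      }
      if (l2 == best) push(ed_tree(edge2, root2))
      FALSE
    })
  }
  list(eds = pool, length = best)
}

# --- random addition sequences ----------------------------------------

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# one RAS tree: random taxon permutation, stepwise addition holding the
# `hold` best partial trees at each step (ties broken first-come in
# canonical branch order)
ras_tree <- function(dat, n, hold = 1L) {
  perm <- sample.int(n)
  beam <- list(ed_init3(perm[1], perm[2], perm[3], n + 1L))
  for (k in 4:n) {
    w <- n + k - 2L
    lens <- numeric(0)
    at <- list()
    for (b in seq_along(beam)) {
      ls <- insertion_lengths(beam[[b]], perm[k], w, dat)
      lens <- c(lens, ls)
      at <- c(at, lapply(seq_along(ls), function(e) c(b, e)))
    }
    keep <- order(lens)[seq_len(min(hold, length(lens)))]
    beam <- lapply(keep, function(i) {
      ed_insert(beam[[at[[i]][1]]], at[[i]][2], perm[k], w)
    })
  }
  beam
}

#' Heuristic parsimony search (random addition + TBR)
#'
#' The workhorse search for matrices too large for [branch_and_bound()]:
#' each replicate builds a random stepwise-addition tree (holding `hold`
#' trees at each step) and swaps it to a local optimum by
#' tree-bisection-reconnection with first-improvement acceptance.  The
#' globally best trees are then closed under equal-length TBR moves so
#' that ties are collected, and deduplicated by topology.  Fully
#' deterministic for a given seed.
#'
#' @param m a [char_matrix()]
#' @param replicates number of random addition sequences (the published
#'   configuration uses 1000)
#' @param hold partial trees held per addition step (published: 1)
#' @param seed integer seed driving all randomness
#' @param max_trees cap on retained tied trees
#' @return an `mp_search` object (see [exhaustive_search()]); the per-
#'   replicate best lengths are attached as `$replicate_lengths`
#' @examples
#' sim <- simulate_matrix(n_taxa = 8, n_char = 30, seed = 1)
#' ras_tbr_search(sim$matrix, replicates = 10, seed = 42)
#' @export
ras_tbr_search <- function(m, replicates = 10L, hold = 1L, seed = 1L,
                           max_trees = 10000L) {
  stopifnot(replicates >= 1L, hold >= 1L)
  n <- n_taxa(m)
  if (n < 4L) {
    res <- exhaustive_search(m, max_trees)
    res$method <- "ras_tbr"
    return(res)
  }
  dat <- kernel_data(m)
  best <- Inf
  best_eds <- list()
  rep_lengths <- numeric(replicates)
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      for (ed in ras_tree(dat, n, hold)) {
        opt <- tbr_descend(ed, dat, n)
        if (opt$length < best) {
          best <- opt$length
          best_eds <- list(opt$ed)
        } else if (opt$length == best) {
          best_eds[[length(best_eds) + 1L]] <- opt$ed
        }
        rep_lengths[r] <- opt$length
      }
    }
  })
  plat <- tbr_plateau(best_eds, best, dat, n, max_trees)
  res <- new_mp_search(dedup_eds(plat$eds, n), plat$length, m, "ras_tbr",
                       NA_integer_, seed,
                       list(replicates = replicates, hold = hold,
                            max_trees = max_trees))
  res$replicate_lengths <- rep_lengths
  res
}

#' One-call parsimony search
#'
#' Dispatches to [exhaustive_search()], [branch_and_bound()] or
#' [ras_tbr_search()]; `"auto"` uses branch-and-bound up to 15 taxa and
#' the heuristic beyond.
#'
#' @inheritParams ras_tbr_search
#' @param method search strategy
#' @return an `mp_search` object
#' @export
mp_search <- function(m, method = c("auto", "exhaustive", "branch_and_bound",
                                    "heuristic"),
                      replicates = 10L, hold = 1L, seed = 1L,
                      max_trees = 10000L) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (n_taxa(m) <= 15L) "branch_and_bound" else "heuristic"
  switch(method,
         exhaustive = exhaustive_search(m, max_trees),
         branch_and_bound = branch_and_bound(m, max_trees),
         heuristic = ras_tbr_search(m, replicates, hold, seed, max_trees))
}
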
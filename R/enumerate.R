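# Exhaustive topology enumeration: the ground-truth oracle for the other
# searches.  Every unrooted binary topology on n taxa is produced exactly
# once by inserting taxon k+1 on each branch of each topology on k taxa;
# the count is (2n-5)!!.

# call f(ed) for every topology over tip ids 1..n (internal ids n+1..)
walk_topologies <- function(n, f) {
  recurse <- function(ed, k) {
    if (k > n) { f(ed); return(invisible(NULL)) }
    w <- n + k - 2L
    for (e in seq_len(nrow(ed$edge))) recurse(ed_insert(ed, e, k, w), k + 1L)
    invisible(NULL)
  }
  recurse(ed_init3(1L, 2L, 3L, n + 1L), 4L)
}

#' Enumerate all unrooted binary topologies
#'
#' Yields every distinct unrooted binary tree on the given taxa exactly
#' once; there are (2n-5)!! of them, so the taxon count is capped at 10.
#'
#' @param taxa character vector of 3 to 10 taxon labels
#' @return a list of `phylo` trees
#' @examples
#' length(enumerate_trees(c("A", "B", "C", "D")))  # 3
#' @export
enumerate_trees <- function(taxa) {
  n <- length(taxa)
  if (n < 3L || n > 10L)
    stop("enumeration supports 3 to 10 taxa (got ", n, ")")
  taxa <- normalize_label(taxa)
  out <- vector("list", prod(seq(2L * n - 5L, 1L, by = -2L)))
  i <- 0L
  walk_topologies(n, function(ed) {
    i <<- i + 1L
    out[[i]] <<- ed_to_phylo(ed, taxa)
  })
  out
}

new_mp_search <- function(eds, length, m, method, evaluated, seed = NA,
                          config = list()) {
  trees <- lapply(eds, ed_to_phylo, taxa = m$taxa)
  structure(list(trees = trees, length = length, method = method,
                 evaluated = evaluated, seed = seed, config = config,
                 taxa = m$taxa),
            class = "mp_search")
}

#' @export
print.mp_search <- function(x, ...) {
  cat("most parsimonious trees:", length(x$trees), "at length", x$length,
      sprintf("(%s, %d trees evaluated)\n", x$method, x$evaluated))
  invisible(x)
}

# deduplicate a list of eds by bipartition-set identity
dedup_eds <- function(eds, ntip) {
  keys <- vapply(eds, ed_topology_key, character(1), ntip = ntip)
  eds[!duplicated(keys)]
}

#' Exhaustive parsimony search
#'
#' Evaluates every unrooted binary topology and returns all trees
#' attaining the minimum length.  Exact but factorial; capped at 10 taxa.
#' Used as the oracle the branch-and-bound and heuristic searches are
#' verified against.
#'
#' @param m a [char_matrix()] with at most 10 taxa
#' @param max_trees cap on the number of tied trees retained
#' @return an object of class `mp_search`: `trees` (list of `phylo`),
#'   `length`, `method`, `evaluated` (topologies scored)
#' @examples
#' sim <- simulate_matrix(n_taxa = 6, n_char = 20, seed = 1)
#' exhaustive_search(sim$matrix)
#' @export
exhaustive_search <- function(m, max_trees = 10000L) {
  n <- n_taxa(m)
  if (n < 3L || n > 10L)
    stop("exhaustive search supports 3 to 10 taxa (got ", n, ")")
  dat <- kernel_data(m)
  best <- Inf
  best_eds <- list()
  count <- 0L
  walk_topologies(n, function(ed) {
    count <<- count + 1L
    len <- ed_length(ed$edge, ed$root, dat)$total_length
    if (len < best) {
      best <<- len
      best_eds <<- list(ed)
    } else if (len == best && length(best_eds) < max_trees) {
      best_eds[[length(best_eds) + 1L]] <<- ed
    }
  })
  new_mp_search(dedup_eds(best_eds, n), best, m, "exhaustive", count)
}
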
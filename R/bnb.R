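# Branch-and-bound parsimony search.  Exact for any taxon count in
# principle (practical to ~15-20 taxa for morphological matrices): taxa
# are added one at a time, and a partial tree whose length already
# exceeds the best complete length is pruned, since adding taxa can only
# add steps.  The incumbent bound is initialized from a deterministic
# greedy addition tree improved by TBR.

#' Branch-and-bound parsimony search
#'
#' Finds the exact minimum length and every most-parsimonious topology
#' without enumerating all trees.  Results are identical to
#' [exhaustive_search()] wherever both run.
#'
#' @param m a [char_matrix()]
#' @param max_trees cap on the number of tied trees retained
#' @param addition_order taxon addition order (indices); default as given in the
#'   matrix
#' @return an `mp_search` object (see [exhaustive_search()])
#' @examples
#' sim <- simulate_matrix(n_taxa = 7, n_char = 20, seed = 1)
#' branch_and_bound(sim$matrix)
#' @export
branch_and_bound <- function(m, max_trees = 10000L,
                             addition_order = seq_len(n_taxa(m))) {
  n <- n_taxa(m)
  if (n < 3L) stop("need at least 3 taxa")
  stopifnot(length(addition_order) == n, !anyDuplicated(addition_order))
  dat <- kernel_data(m)

  # incumbent: deterministic greedy addition + TBR descent
  seed_ed <- greedy_addition(addition_order, dat, n)
  seed_ed <- tbr_descend(seed_ed, dat, n)$ed
  best <- ed_length(seed_ed$edge, seed_ed$root, dat)$total_length
  best_eds <- list()
  count <- 0L

  recurse <- function(ed, k) {
    if (k > n) {
      count <<- count + 1L
      len <- ed_length(ed$edge, ed$root, dat)$total_length
      if (len < best) {
        best <<- len
        best_eds <<- list(ed)
      } else if (len == best && length(best_eds) < max_trees) {
        best_eds[[length(best_eds) + 1L]] <<- ed
      }
      return(invisible(NULL))
    }
    tip <- addition_order[k]
    w <- n + k - 2L
    nedge <- nrow(ed$edge)
    lens <- insertion_lengths(ed, tip, w, dat)
    count <<- count + nedge
    for (e in order(lens)) {            # best-first sharpens the bound
      if (lens[e] <= best) recurse(ed_insert(ed, e, tip, w), k + 1L)
    }
    invisible(NULL)
  }
  recurse(ed_init3(addition_order[1], addition_order[2], addition_order[3], n + 1L), 4L)

  new_mp_search(dedup_eds(best_eds, n), best, m, "branch_and_bound", count)
}

# deterministic greedy stepwise addition (first-best placement)
greedy_addition <- function(order, dat, n) {
  ed <- ed_init3(order[1], order[2], order[3], n + 1L)
  k <- 4L
  while (k <= length(order)) {
    w <- n + k - 2L
    lens <- insertion_lengths(ed, order[k], w, dat)
    ed <- ed_insert(ed, which.min(lens), order[k], w)
    k <- k + 1L
  }
  ed
}
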
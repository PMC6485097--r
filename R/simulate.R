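# Synthetic morphological matrices with known true trees: a per-branch
# Bernoulli jump process (all branch lengths 1), optional masking of
# cells to missing and widening to adjacent-state polymorphisms, and a
# tooth-only-taxon degradation mode mimicking fossil taxa coded from
# isolated teeth.

#' Simulate a morphological character matrix on a known tree
#'
#' Characters evolve independently down a random (or supplied) unrooted
#' binary topology: the root state is uniform on `0:(n_states-1)`; along
#' each branch the state jumps, with probability `change_prob`, to a
#' uniformly chosen different state (ordered model: one step up or down).
#' Afterwards `missing_frac` of cells are masked to `?` and
#' `polymorphic_frac` are widened by one adjacent state, mimicking real
#' polymorphic codings such as `(0/1)`.  Everything is reproducible from
#' `seed`.
#'
#' @param n_taxa taxon count for a random topology (ignored when `tree`
#'   is given); simulated taxa are labelled `t1..tn`
#' @param n_char number of characters
#' @param n_states states per character (>= 2)
#' @param change_prob per-branch change probability in [0, 1]
#' @param missing_frac,polymorphic_frac cell fractions in [0, 1), summing
#'   below 1
#' @param ordered simulate (and flag) ordered characters?
#' @param tree optional true tree (`phylo`, taken as unrooted)
#' @param seed integer seed
#' @return a list: `matrix` (a [char_matrix()]), `tree` (the true
#'   `phylo`), `config` (the arguments)
#' @examples
#' sim <- simulate_matrix(n_taxa = 8, n_char = 25, change_prob = 0.1, seed = 1)
#' sim$matrix
#' @export
simulate_matrix <- function(n_taxa = 12L, n_char = 100L, n_states = 2L,
                            change_prob = 0.1, missing_frac = 0,
                            polymorphic_frac = 0, ordered = FALSE,
                            tree = NULL, seed = 1L) {
  stopifnot(n_states >= 2L, change_prob >= 0, change_prob <= 1,
            missing_frac >= 0, polymorphic_frac >= 0,
            missing_frac + polymorphic_frac < 1, n_char >= 1L)
  with_seed(seed, {
    if (is.null(tree)) {
      tree <- ape::rtopology(n_taxa, rooted = FALSE,
                             tip.label = paste0("t", seq_len(n_taxa)))
    }
    ntip <- length(tree$tip.label)
    ptree <- ape::reorder.phylo(tree, "postorder")
    nnode_all <- max(ptree$edge)
    root <- ntip + 1L
    states <- matrix(NA_integer_, nnode_all, n_char)
    states[root, ] <- sample.int(n_states, n_char, replace = TRUE) - 1L
    # preorder sweep: parents before children
    for (e in rev(seq_len(nrow(ptree$edge)))) {
      p <- ptree$edge[e, 1]; v <- ptree$edge[e, 2]
      s <- states[p, ]
      jump <- runif(n_char) < change_prob
      if (any(jump)) {
        if (ordered) {
          up <- s[jump] + ifelse(runif(sum(jump)) < 0.5, 1L, -1L)
          up[up < 0L] <- 1L
          up[up > n_states - 1L] <- n_states - 2L
          s[jump] <- up
        } else {
          s[jump] <- vapply(s[jump], function(cur) {
            sample(setdiff(0:(n_states - 1L), cur), 1L)
          }, integer(1))
        }
      }
      states[v, ] <- s
    }
    tip_states <- states[seq_len(ntip), , drop = FALSE]
    grid <- matrix(as.character(tip_states), ntip, n_char)
    ncell <- length(grid)
    shuffle <- sample.int(ncell)
    n_miss <- round(missing_frac * ncell)
    n_poly <- round(polymorphic_frac * ncell)
    if (n_miss > 0) grid[shuffle[seq_len(n_miss)]] <- "?"
    if (n_poly > 0) {
      for (idx in shuffle[n_miss + seq_len(n_poly)]) {
        cur <- tip_states[idx]
        adj <- if (cur < n_states - 1L) cur + 1L else cur - 1L
        grid[idx] <- paste0("{", min(cur, adj), " ", max(cur, adj), "}")
      }
    }
    rownames(grid) <- ptree$tip.label
    list(matrix = char_matrix(grid, ordered = ordered),
         tree = tree,
         config = list(n_taxa = ntip, n_char = n_char, n_states = n_states,
                       change_prob = change_prob, missing_frac = missing_frac,
                       polymorphic_frac = polymorphic_frac, ordered = ordered,
                       seed = seed))
  })
}

#' Simulate a fully congruent (homoplasy-free) matrix
#'
#' Every character marks one internal branch of the tree: state 1 inside
#' the clade, 0 outside, so the matrix fits the tree with no homoplasy
#' and every character is an uncontradicted binary synapomorphy.  The
#' first characters cycle through all non-trivial clades (guaranteeing
#' coverage); the rest are drawn uniformly.
#'
#' @param tree an unrooted binary `phylo`
#' @param n_char number of characters (>= number of internal branches)
#' @param seed integer seed
#' @return a list: `matrix`, `tree`
#' @export
congruent_matrix <- function(tree, n_char, seed = 1L) {
  taxa <- tree$tip.label
  sides <- phylo_splits(tree, taxa)
  if (!length(sides)) stop("tree has no internal branches")
  stopifnot(n_char >= length(sides))
  with_seed(seed, {
    pick <- c(seq_along(sides),
              sample.int(length(sides), n_char - length(sides), replace = TRUE))
    grid <- matrix("0", length(taxa), n_char)
    for (j in seq_len(n_char)) grid[sides[[pick[j]]], j] <- "1"
    rownames(grid) <- taxa
    list(matrix = char_matrix(grid), tree = tree)
  })
}

#' Degrade taxa to tooth-only coverage
#'
#' For fossil taxa known only from isolated teeth, every character
#' outside the dentition-related subset is unobservable.  This helper
#' masks, for the chosen taxa, all characters outside `keep_chars` to
#' missing — mirroring published tooth-only codings that cover 22 of 103
#' characters (about 80% of cells missing).
#'
#' @param m a [char_matrix()]
#' @param taxa taxon labels (or indices) to degrade
#' @param keep_chars character indices that remain observable; default: a
#'   fixed-seed sample of `ceiling(22/103 * n_char(m))` characters
#' @param seed seed for the default `keep_chars` sample
#' @return the degraded matrix
#' @export
degrade_to_teeth_taxa <- function(m, taxa, keep_chars = NULL, seed = 1L) {
  i <- if (is.character(taxa)) match(normalize_label(taxa), m$taxa) else as.integer(taxa)
  if (anyNA(i)) stop("unknown taxa: ", paste(taxa[is.na(match(normalize_label(taxa), m$taxa))], collapse = ", "))
  if (is.null(keep_chars)) {
    keep_chars <- with_seed(seed,
                            sort(sample.int(n_char(m), ceiling(22 / 103 * n_char(m)))))
  }
  keep_chars <- as.integer(keep_chars)
  if (any(keep_chars < 1L | keep_chars > n_char(m)))
    stop("keep_chars out of range")
  drop <- setdiff(seq_len(n_char(m)), keep_chars)
  for (j in drop) {
    m$bits[i, j] <- full_range_bits(m$specs$max_state[j])
    m$missing[i, j] <- TRUE
    m$gap[i, j] <- FALSE
  }
  validate_char_matrix(m)
}
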
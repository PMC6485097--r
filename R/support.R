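# Clade support: Bremer decay via converse-constraint searches and
# nonparametric character bootstrap.

# Canonical clade label for cross-table joins: the side of the split not
# containing the alphabetically first taxon, labels sorted.
canonical_split_label <- function(side, taxa) {
  labs <- taxa[side]
  ref <- sort(taxa)[1]
  if (ref %in% labs) labs <- setdiff(taxa, labs)
  paste(sort(labs), collapse = " ")
}

# kernel data for a set of splits as synthetic binary characters
splits_dat <- function(sides, ntip) {
  bits <- matrix(1L, ntip, length(sides))
  for (j in seq_along(sides)) bits[sides[[j]], j] <- 2L
  list(bits = bits, lo = matrix(0L, ntip, length(sides)),
       hi = matrix(0L, ntip, length(sides)),
       ordered = rep(FALSE, length(sides)), weights = rep(1, length(sides)))
}

#' Bremer decay values for the supported clades
#'
#' For each bipartition in the strict consensus of the most-parsimonious
#' trees, the Bremer (decay) value is the length of the best tree that
#' does NOT contain the clade, minus the optimal length.  With few taxa
#' the converse search is exact (all topologies are enumerated in one
#' sweep); beyond `exact_max_taxa` each clade is attacked by a heuristic
#' RAS+TBR search whose objective penalizes trees containing it, and
#' values above `cap` are reported censored.
#'
#' @param m a [char_matrix()]
#' @param search an `mp_search` result for `m` (from [mp_search()] and
#'   friends)
#' @param exact_max_taxa largest taxon count for the enumerate route
#' @param replicates,hold,seed heuristic search settings (converse route)
#' @param cap report `>= cap` as censored
#' @return a data frame of class `support_table`: `clade` (labels),
#'   `size`, `bremer`, `censored`
#' @examples
#' sim <- simulate_matrix(n_taxa = 6, n_char = 30, seed = 7)
#' sr <- branch_and_bound(sim$matrix)
#' bremer_supports(sim$matrix, sr)
#' @export
bremer_supports <- function(m, search, exact_max_taxa = 10L,
                            replicates = 10L, hold = 1L, seed = 1L,
                            cap = 20L) {
  stopifnot(inherits(search, "mp_search"))
  n <- n_taxa(m)
  cons <- strict_consensus(search$trees)
  # splits indexed against m$taxa
  sides <- phylo_splits(cons, m$taxa)
  if (!length(sides)) {
    return(structure(data.frame(clade = character(0), size = integer(0),
                                bremer = numeric(0), censored = logical(0)),
                     class = c("support_table", "data.frame")))
  }
  L_min <- search$length
  best_without <- rep(Inf, length(sides))
  if (n <= exact_max_taxa) {
    dat <- kernel_data(m)
    sdat <- splits_dat(sides, n)
    walk_topologies(n, function(ed) {
      len <- ed_length(ed$edge, ed$root, dat)$total_length
      has <- C_pars_length(ed$edge, ed$root, sdat$bits, sdat$lo, sdat$hi,
                           sdat$ordered, sdat$weights)$per_char_steps == 1L
      upd <- !has & len < best_without
      best_without[upd] <<- len
    })
  } else {
    dat <- kernel_data(m)
    for (j in seq_along(sides)) {
      best <- Inf
      with_seed(seed + j, {
        for (r in seq_len(replicates)) {
          for (ed in ras_tree(dat, n, hold)) {
            opt <- tbr_descend(ed, dat, n, constraint = sides[[j]])
            if (opt$length < best) best <- opt$length
          }
        }
      })
      best_without[j] <- best
    }
  }
  bremer <- best_without - L_min
  censored <- !is.finite(bremer) | bremer > cap
  bremer[censored] <- cap
  structure(data.frame(
    clade = vapply(sides, canonical_split_label, character(1), taxa = m$taxa),
    size = lengths(sides),
    bremer = as.numeric(bremer),
    censored = censored
  ), class = c("support_table", "data.frame"))
}

#' Nonparametric character bootstrap
#'
#' Resamples characters with replacement to the original count, runs a
#' reduced heuristic search on each pseudoreplicate, and records the
#' bipartitions of the strict consensus of that replicate's optimal
#' trees.  Clade support is the percentage of replicates containing the
#' bipartition; a majority-rule consensus with those percentages as node
#' labels is attached.
#'
#' @param m a [char_matrix()]
#' @param replicates bootstrap pseudoreplicates (published analyses
#'   commonly use 1000)
#' @param seed integer seed; every replicate's resampling and search
#'   derives from it
#' @param search_replicates,hold per-replicate RAS+TBR settings (reduced
#'   from a full search, standard practice)
#' @param max_trees tie cap per replicate
#' @param min_freq clades at or above this percentage enter the output
#'   table (the majority-rule tree always uses > 50)
#' @return a list of class `bootstrap_support`: `table` (data frame:
#'   `clade`, `size`, `bootstrap` percent), `tree` (majority-rule `phylo`
#'   with percentages as node labels), `replicates`, `seed`
#' @examples
#' sim <- simulate_matrix(n_taxa = 6, n_char = 40, seed = 3)
#' bs <- bootstrap_supports(sim$matrix, replicates = 20, seed = 5)
#' bs$table
#' @export
bootstrap_supports <- function(m, replicates = 1000L, seed = 1L,
                               search_replicates = 10L, hold = 1L,
                               max_trees = 100L, min_freq = 5) {
  n <- n_taxa(m)
  nch <- n_char(m)
  counts <- new.env(parent = emptyenv())
  sides_seen <- list()
  with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max, replicates)
    for (r in seq_len(replicates)) {
      cols <- sample.int(nch, nch, replace = TRUE)
      mrep <- subset_matrix(m, chars = cols)
      sr <- ras_tbr_search(mrep, replicates = search_replicates, hold = hold,
                           seed = rep_seeds[r], max_trees = max_trees)
      cons <- strict_consensus(sr$trees)
      for (side in phylo_splits(cons, m$taxa)) {
        key <- split_key(side)
        if (is.null(counts[[key]])) {
          counts[[key]] <- 1L
          sides_seen[[key]] <- side
        } else counts[[key]] <- counts[[key]] + 1L
      }
    }
  })
  keys <- ls(counts)
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  sides <- sides_seen[keys]
  pct <- 100 * cnt / replicates
  keep_tree <- pct > 50
  tree <- clades_to_phylo(sides[keep_tree], m$taxa,
                          labels = round(pct[keep_tree], 1))
  keep_tab <- pct >= min_freq
  tab <- data.frame(
    clade = vapply(sides[keep_tab], canonical_split_label, character(1),
                   taxa = m$taxa),
    size = lengths(sides[keep_tab]),
    bootstrap = round(pct[keep_tab], 1)
  )
  tab <- tab[order(-tab$bootstrap, tab$clade), ]
  rownames(tab) <- NULL
  structure(list(table = tab, tree = tree, replicates = replicates,
                 seed = seed),
            class = "bootstrap_support")
}

#' @export
print.bootstrap_support <- function(x, ...) {
  cat("character bootstrap:", x$replicates, "replicates (seed", x$seed, ")\n")
  print(x$table)
  invisible(x)
}

#' @export
print.support_table <- function(x, ...) {
  cat("Bremer decay values:\n")
  y <- as.data.frame(x)
  y$bremer <- ifelse(y$censored, paste0(">", y$bremer), y$bremer)
  print(y[c("clade", "size", "bremer")])
  invisible(x)
}
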
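test_that("uncontradicted characters give Bremer values equal to their count", {
  # homoplasy-free matrix: each clade supported by k identical binary
  # characters decays only after k extra steps
  tr <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  taxa <- sort(tr$tip.label)
  counts <- c(3L, 1L, 2L)  # copies per clade: AB, CD, EF
  sides <- maxpars:::phylo_splits(tr, taxa)
  grid <- matrix("0", 6, sum(counts), dimnames = list(taxa, NULL))
  j <- 0L
  for (s in seq_along(sides)) {
    for (rep in seq_len(counts[s])) {
      j <- j + 1L
      grid[sides[[s]], j] <- "1"
    }
  }
  m <- char_matrix(grid)
  sr <- exhaustive_search(m)
  br <- bremer_supports(m, sr)
  got <- setNames(br$bremer, br$clade)
  lab <- function(side) maxpars:::canonical_split_label(side, taxa)
  expect_equal(unname(got[vapply(sides, lab, character(1))]),
               as.numeric(counts))
  expect_false(any(br$censored))
})

test_that("Bremer via converse constraints equals full enumeration", {
  for (i in 1:6) {
    n <- if (i <= 3) 6L else 7L
    sim <- simulate_matrix(n_taxa = n, n_char = 15, n_states = 2,
                           change_prob = 0.3, seed = 800 + i)
    m <- sim$matrix
    sr <- branch_and_bound(m)
    exact <- bremer_supports(m, sr)                     # enumerate route
    if (!nrow(exact)) next
    heur <- bremer_supports(m, sr, exact_max_taxa = 0L, # constrained route
                            replicates = 10L, seed = i)
    expect_equal(heur$bremer[match(exact$clade, heur$clade)], exact$bremer)
    # independent oracle: lengths of every topology via brute force
    taxa <- m$taxa
    trees <- all_topologies(taxa)
    lens <- vapply(trees, bf_length, numeric(1), m = m)
    for (r in seq_len(nrow(exact))) {
      clade_labs <- strsplit(exact$clade[r], " ")[[1]]
      side_idx <- sort(match(clade_labs, taxa))
      lacks <- vapply(trees, function(t) {
        keys <- split_keys(t, taxa)
        !(maxpars:::split_key(side_idx) %in% keys ||
            maxpars:::split_key(sort(match(setdiff(taxa, clade_labs), taxa)))
          %in% keys)
      }, logical(1))
      expect_equal(exact$bremer[r], min(lens[lacks]) - sr$length)
    }
  }
})

test_that("clades absent from the strict consensus are not assigned support", {
  # two equally parsimonious resolutions: conflicting clade has Bremer 0,
  # so only strict-consensus clades are reported
  grid <- rbind(A = c("0", "0", "1"), B = c("0", "1", "1"),
                C = c("1", "1", "0"), D = c("1", "0", "0"),
                E = c("0", "0", "0"))
  m <- char_matrix(grid)
  sr <- exhaustive_search(m)
  br <- bremer_supports(m, sr)
  cons_labels <- vapply(maxpars:::phylo_splits(strict_consensus(sr$trees), m$taxa),
                        maxpars:::canonical_split_label, character(1),
                        taxa = m$taxa)
  expect_setequal(br$clade, cons_labels)
  expect_true(all(br$bremer >= 1))
})

test_that("duplicating every character doubles Bremer support", {
  pf <- perfect_fixture(n_taxa = 6, n_char = 8, seed = 10)
  m1 <- pf$matrix
  m2 <- subset_matrix(m1, chars = rep(seq_len(n_char(m1)), 2))
  b1 <- bremer_supports(m1, exhaustive_search(m1))
  b2 <- bremer_supports(m2, exhaustive_search(m2))
  expect_equal(b2$bremer[match(b1$clade, b2$clade)], 2 * b1$bremer)
})

test_that("bootstrap is deterministic per seed and resamples to full size", {
  sim <- simulate_matrix(n_taxa = 6, n_char = 30, change_prob = 0.2, seed = 21)
  a <- bootstrap_supports(sim$matrix, replicates = 15, seed = 3)
  b <- bootstrap_supports(sim$matrix, replicates = 15, seed = 3)
  expect_identical(a$table, b$table)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  c <- bootstrap_supports(sim$matrix, replicates = 15, seed = 4)
  expect_false(identical(a$table, c$table) &&
                 identical(ape::write.tree(a$tree), ape::write.tree(c$tree)))
  # a resampled pseudoreplicate keeps the original character count
  mrep <- maxpars:::with_seed(9, subset_matrix(
    sim$matrix, chars = sample.int(n_char(sim$matrix), n_char(sim$matrix),
                                   replace = TRUE)))
  expect_equal(n_char(mrep), n_char(sim$matrix))
})

test_that("a congruent matrix bootstraps every true clade to high support", {
  pf <- perfect_fixture(n_taxa = 7, n_char = 60, seed = 14)
  bs <- bootstrap_supports(pf$matrix, replicates = 100, seed = 6,
                           search_replicates = 3)
  truth <- vapply(maxpars:::phylo_splits(pf$tree, pf$matrix$taxa),
                  maxpars:::canonical_split_label, character(1),
                  taxa = pf$matrix$taxa)
  got <- bs$table$bootstrap[match(truth, bs$table$clade)]
  expect_false(anyNA(got))
  expect_true(all(got >= 95))
})

test_that("bootstrap frequencies are insensitive to character order", {
  sim <- simulate_matrix(n_taxa = 6, n_char = 40, change_prob = 0.15, seed = 17)
  m1 <- sim$matrix
  m2 <- subset_matrix(m1, chars = rev(seq_len(n_char(m1))))
  b1 <- bootstrap_supports(m1, replicates = 60, seed = 11)
  b2 <- bootstrap_supports(m2, replicates = 60, seed = 12)
  shared <- intersect(b1$table$clade[b1$table$bootstrap >= 60],
                      b2$table$clade[b2$table$bootstrap >= 60])
  expect_gt(length(shared), 0L)
  d <- abs(b1$table$bootstrap[match(shared, b1$table$clade)] -
             b2$table$bootstrap[match(shared, b2$table$clade)])
  expect_true(all(d <= 15))  # sampling noise only
})
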
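test_that("topology enumeration yields the double-factorial counts once each", {
  for (n in 4:6) {
    trees <- enumerate_trees(paste0("t", 1:n))
    expect_length(trees, prod(seq(2 * n - 5, 1, by = -2)))
    keys <- vapply(trees, topo_key, character(1), taxa = paste0("t", 1:n))
    expect_false(anyDuplicated(keys) > 0)
  }
  expect_error(enumerate_trees(paste0("t", 1:11)), "3 to 10")
  expect_error(enumerate_trees(c("a", "b")), "3 to 10")
})

test_that("exhaustive search recovers a perfect phylogeny at its minimum length", {
  pf <- perfect_fixture(n_taxa = 6, n_char = 10, seed = 3)
  es <- exhaustive_search(pf$matrix)
  keys <- vapply(es$trees, topo_key, character(1), taxa = pf$matrix$taxa)
  expect_true(topo_key(pf$tree, pf$matrix$taxa) %in% keys)
  mins <- sum(vapply(seq_len(n_char(pf$matrix)), function(j) {
    min_steps(matrix_column(pf$matrix, j))
  }, integer(1)))
  expect_equal(es$length, mins)
})

test_that("an all-invariant matrix ties every topology at length zero", {
  m <- char_matrix(matrix("0", 6, 4, dimnames = list(paste0("t", 1:6))))
  es <- exhaustive_search(m)
  expect_equal(es$length, 0)
  expect_length(es$trees, 105L)
  bb <- branch_and_bound(m)
  expect_equal(bb$length, 0)
  expect_length(bb$trees, 105L)
})

test_that("branch-and-bound matches exhaustive search on random matrices", {
  for (i in 1:12) {
    set.seed(400 + i)
    n <- sample(6:8, 1)
    sim <- simulate_matrix(n_taxa = n, n_char = sample(8:15, 1),
                           n_states = sample(2:3, 1), change_prob = 0.25,
                           missing_frac = 0.05, polymorphic_frac = 0.03,
                           seed = 400 + i)
    m <- sim$matrix
    es <- exhaustive_search(m)
    bb <- branch_and_bound(m)
    expect_equal(bb$length, es$length)
    expect_setequal(vapply(bb$trees, topo_key, character(1), taxa = m$taxa),
                    vapply(es$trees, topo_key, character(1), taxa = m$taxa))
    # soundness vs the brute-force oracle (kept to n = 6, where the
    # assignment enumeration is affordable)
    if (n == 6 && i <= 6) {
      expect_equal(es$length, min(vapply(all_topologies(m$taxa), bf_length,
                                         numeric(1), m = m)))
    }
  }
})

test_that("a one-character matrix is optimized to its minimum over topologies", {
  m <- char_matrix(matrix(c("0", "0", "1", "1", "2", "2"), ncol = 1,
                          dimnames = list(paste0("t", 1:6))))
  bb <- branch_and_bound(m)
  expect_equal(bb$length,
               min(vapply(all_topologies(m$taxa), bf_length, numeric(1), m = m)))
  expect_equal(bb$length, 2)  # three states force two changes
})

test_that("heuristic search equals branch-and-bound and is seed-stable", {
  for (i in 1:6) {
    sim <- simulate_matrix(n_taxa = 7, n_char = 12, n_states = 2,
                           change_prob = 0.3, seed = 500 + i)
    m <- sim$matrix
    bb <- branch_and_bound(m)
    rs <- ras_tbr_search(m, replicates = 15, seed = i)
    expect_equal(rs$length, bb$length)
    expect_setequal(vapply(rs$trees, topo_key, character(1), taxa = m$taxa),
                    vapply(bb$trees, topo_key, character(1), taxa = m$taxa))
  }
  sim <- simulate_matrix(n_taxa = 8, n_char = 15, change_prob = 0.3, seed = 77)
  a <- ras_tbr_search(sim$matrix, replicates = 5, seed = 9)
  b <- ras_tbr_search(sim$matrix, replicates = 5, seed = 9)
  expect_equal(lapply(a$trees, ape::write.tree), lapply(b$trees, ape::write.tree))
  expect_equal(a$replicate_lengths, b$replicate_lengths)
})

test_that("a single greedy replicate recovers a homoplasy-free tree", {
  pf <- perfect_fixture(n_taxa = 8, n_char = 14, seed = 6)
  rs <- ras_tbr_search(pf$matrix, replicates = 1, hold = 1, seed = 2)
  expect_equal(vapply(rs$trees, topo_key, character(1), taxa = pf$matrix$taxa),
               topo_key(pf$tree, pf$matrix$taxa))
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),((C,D),E),F);")
  expect_equal(topo_key(strict_consensus(list(t1, t1)), sort(t1$tip.label)),
               topo_key(t1, sort(t1$tip.label)))
  t2 <- ape::read.tree(text = "((A,B),(C,(D,E)),F);")
  cons <- strict_consensus(list(t1, t2))
  taxa <- sort(t1$tip.label)
  expect_setequal(split_keys(cons, taxa),
                  intersect(split_keys(t1, taxa), split_keys(t2, taxa)))
  # all topologies at n = 5 share nothing: star tree
  star <- strict_consensus(enumerate_trees(paste0("t", 1:5)))
  expect_length(split_keys(star, paste0("t", 1:5)), 0L)
  expect_error(strict_consensus(list(t1, ape::rtree(4))), "mismatched")
})

test_that("strict consensus matches ape's implementation", {
  for (i in 1:5) {
    sim <- simulate_matrix(n_taxa = 7, n_char = 8, change_prob = 0.3,
                           seed = 600 + i)
    es <- exhaustive_search(sim$matrix)
    taxa <- sort(sim$matrix$taxa)
    mine <- strict_consensus(es$trees)
    theirs <- ape::consensus(es$trees)
    expect_setequal(split_keys(mine, taxa), split_keys(theirs, taxa))
  }
})

test_that("majority-rule consensus attaches correct frequencies", {
  t1 <- ape::read.tree(text = "((A,B),((C,D),E),F);")
  t2 <- ape::read.tree(text = "((A,B),(C,(D,E)),F);")
  maj <- majority_rule_consensus(list(t1, t1, t1, t2))
  fr <- attr(maj, "frequencies")
  expect_true(all(fr$frequency > 50))
  ab <- fr$frequency[grepl("^A B$|^C D E F$", fr$clade)]
  expect_equal(ab, 100)
  cd <- fr$frequency[fr$clade == "C D"]
  expect_equal(cd, 75)
  # threshold 1 equals the strict consensus
  taxa <- sort(t1$tip.label)
  expect_setequal(split_keys(majority_rule_consensus(list(t1, t2), 1), taxa),
                  split_keys(strict_consensus(list(t1, t2)), taxa))
})

test_that("TBR descent never increases length along a replicate", {
  sim <- simulate_matrix(n_taxa = 9, n_char = 20, change_prob = 0.3, seed = 31)
  m <- sim$matrix
  dat <- maxpars:::kernel_data(m)
  maxpars:::with_seed(5, {
    for (r in 1:3) {
      ed <- maxpars:::ras_tree(dat, n_taxa(m), 1L)[[1]]
      start <- maxpars:::ed_length(ed$edge, ed$root, dat)$total_length
      opt <- maxpars:::tbr_descend(ed, dat, n_taxa(m))
      expect_lte(opt$length, start)
    }
  })
})

test_that("low-homoplasy simulations recover the true clades", {
  # smoke-scale version of the recovery study (the full 100-run study at
  # the stated simulation conditions runs with the acceptance checks)
  hits <- 0; total <- 0
  for (i in 1:10) {
    sim <- simulate_matrix(n_taxa = 12, n_char = 200, change_prob = 0.05,
                           seed = 700 + i)
    rs <- ras_tbr_search(sim$matrix, replicates = 3, seed = i)
    cons <- strict_consensus(rs$trees)
    truth <- split_keys(sim$tree, sim$matrix$taxa)
    hits <- hits + length(intersect(split_keys(cons, sim$matrix$taxa), truth))
    total <- total + length(truth)
  }
  expect_gte(hits / total, 0.9)
})
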
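quartet <- ape::read.tree(text = "((A,B),(C,D));")

test_that("Fitch steps match hand-checkable quartet cases", {
  expect_equal(as.integer(fitch_steps(quartet, list(A = 0, B = 0, C = 1, D = 1))), 1L)
  expect_equal(as.integer(fitch_steps(quartet, list(A = 0, B = 1, C = 0, D = 1))), 2L)
  expect_equal(as.integer(fitch_steps(quartet, list(A = 2, B = 2, C = 2, D = 2))), 0L)
  expect_equal(as.integer(fitch_steps(quartet, list(A = 0, B = NA, C = 1, D = NA))), 1L)
  expect_error(fitch_steps(quartet, list(A = 0, B = 0, C = 1)), "no column entry")
})

test_that("Wagner steps respect ordered-state geometry", {
  expect_equal(wagner_steps(quartet, list(A = 0, B = 0, C = 2, D = 2)), 2L)
  expect_equal(wagner_steps(quartet, list(A = 1, B = 1, C = 1, D = 1)), 0L)
  # a column spanning states 0..r needs at least r steps
  col <- list(A = 0, B = 1, C = 2, D = 3)
  expect_gte(wagner_steps(quartet, col), 3L)
})

test_that("Fitch and Wagner equal brute-force minimization on small trees", {
  # all 15 five-leaf topologies x random columns over <= 3 states,
  # including missing and polymorphic cells
  labels <- paste0("t", 1:5)
  trees <- all_topologies(labels)
  set.seed(101)
  for (tr in trees) {
    for (rep in 1:6) {
      col <- lapply(labels, function(x) {
        r <- runif(1)
        if (r < 0.15) NA
        else if (r < 0.3) sort(sample(0:2, 2))
        else sample(0:2, 1)
      })
      names(col) <- labels
      expect_equal(as.integer(fitch_steps(tr, col)),
                   bf_steps(tr, col, ordered = FALSE, max_state = 2))
      expect_equal(as.integer(wagner_steps(tr, col)),
                   bf_steps(tr, col, ordered = TRUE, max_state = 2))
    }
  }
  # all 105 six-leaf topologies x a fixed column set
  labels6 <- paste0("t", 1:6)
  trees6 <- all_topologies(labels6)
  set.seed(202)
  cols6 <- replicate(4, {
    col <- lapply(labels6, function(x) sample(0:2, 1))
    names(col) <- labels6
    col
  }, simplify = FALSE)
  for (tr in trees6) {
    for (col in cols6) {
      expect_equal(as.integer(fitch_steps(tr, col)),
                   bf_steps(tr, col, ordered = FALSE, max_state = 2))
    }
  }
})

test_that("tree_length sums weighted per-character steps and matches brute force", {
  sim <- simulate_matrix(n_taxa = 6, n_char = 12, n_states = 2,
                         change_prob = 0.3, seed = 5)
  m <- sim$matrix
  fit <- tree_length(sim$tree, m)
  expect_equal(fit$total_length, sum(fit$per_char_steps))
  expect_equal(fit$total_length, bf_length(sim$tree, m))
  # weights scale linearly
  m2 <- set_weights(m, 2)
  expect_equal(tree_length(sim$tree, m2)$total_length, 2 * fit$total_length)
  # a single-character matrix's length is that character's steps
  m1 <- subset_matrix(m, chars = 1L)
  expect_equal(tree_length(sim$tree, m1)$total_length,
               as.numeric(fit$per_char_steps[1]))
  expect_error(tree_length(ape::rtree(5), m), "not in tree")
})

test_that("tree length is invariant to re-rooting and leaf order", {
  sim <- simulate_matrix(n_taxa = 7, n_char = 15, n_states = 3,
                         change_prob = 0.3, seed = 9)
  m <- sim$matrix
  base <- tree_length(sim$tree, m)$total_length
  rooted <- root_on_outgroup(sim$tree, "t3")
  expect_equal(tree_length(rooted, m)$total_length, base)
  rot <- ape::rotateConstr(sim$tree, rev(sort(sim$tree$tip.label)))
  expect_equal(tree_length(rot, m)$total_length, base)
})

test_that("column-wise and kernel routes agree (dual implementation check)", {
  sim <- simulate_matrix(n_taxa = 8, n_char = 20, n_states = 3,
                         change_prob = 0.3, missing_frac = 0.1,
                         polymorphic_frac = 0.05, seed = 12)
  m <- sim$matrix
  m <- set_ordered(m, TRUE, chars = seq(2, 20, by = 4))
  fit <- tree_length(sim$tree, m)
  for (j in seq_len(n_char(m))) {
    col <- matrix_column(m, j)
    expected <- if (m$specs$ordered[j]) wagner_steps(sim$tree, col)
                else as.integer(fitch_steps(sim$tree, col))
    expect_equal(as.integer(fit$per_char_steps[j]), as.integer(expected))
  }
  # the Sankoff dynamic program is a third, independent route
  sk <- maxpars:::sankoff_length(sim$tree, m)
  expect_equal(as.numeric(sk$per_char_steps), as.numeric(fit$per_char_steps))
})

test_that("min_steps handles polymorphism and ordered ranges", {
  expect_equal(min_steps(list(0, 1, 2)), 2L)
  expect_equal(min_steps(list(0, c(0, 1), 1)), 1L)
  expect_equal(min_steps(list(c(0, 1), c(1, 2))), 0L)
  expect_equal(min_steps(list(0, 2), ordered = TRUE), 2L)
  expect_equal(min_steps(list(c(0, 2), 1), ordered = TRUE), 0L)
  expect_equal(min_steps(list(NA, 1, NA)), 0L)
})

test_that("max_steps equals the worst tree over exhaustive enumeration", {
  # binary column, seven taxa, four 0s / three 1s -> 3
  col7 <- as.list(c(0, 0, 0, 0, 1, 1, 1))
  names(col7) <- paste0("t", 1:7)
  expect_equal(max_steps(col7), 3L)
  expect_equal(max_steps(list(1, 1, 1)), 0L)
  expect_equal(max_steps(list(NA, 0, NA)), 0L)
  # oracle: maximum of brute-force steps over all topologies (n = 6)
  labels <- paste0("t", 1:6)
  trees <- all_topologies(labels)
  set.seed(33)
  for (rep in 1:5) {
    col <- lapply(labels, function(x) sample(0:2, 1))
    names(col) <- labels
    worst_unord <- max(vapply(trees, bf_steps, numeric(1), column = col,
                              ordered = FALSE, max_state = 2))
    worst_ord <- max(vapply(trees, bf_steps, numeric(1), column = col,
                            ordered = TRUE, max_state = 2))
    expect_equal(as.integer(worst_unord), max_steps(col))
    expect_equal(as.integer(worst_ord), max_steps(col, ordered = TRUE))
  }
})

test_that("per-character bounds m_i <= s_i <= g_i hold across random data", {
  for (seed in 1:6) {
    sim <- simulate_matrix(n_taxa = 7, n_char = 25, n_states = 3,
                           change_prob = 0.35, missing_frac = 0.15,
                           polymorphic_frac = 0.05, seed = seed)
    m <- sim$matrix
    es <- ensemble_stats(m, sim$tree)
    expect_true(all(es$per_char$min_steps <= es$per_char$steps))
    expect_true(all(es$per_char$steps <= es$per_char$max_steps))
    expect_true(es$M <= es$S && es$S <= es$G)
    expect_gt(es$CI, 0)
    expect_lte(es$CI, 1)
  }
})

test_that("homoplasy-free matrices give CI = RI = 1 and extra missing data is inert", {
  pf <- perfect_fixture()
  es <- ensemble_stats(pf$matrix, pf$tree)
  expect_equal(es$CI, 1)
  expect_equal(es$RI, 1)
  # adding an all-missing character changes nothing
  grid <- matrix("?", n_taxa(pf$matrix), 1, dimnames = list(pf$matrix$taxa))
  m2 <- pf$matrix
  m2$bits <- cbind(m2$bits, maxpars:::full_range_bits(1L))
  m2$missing <- cbind(m2$missing, TRUE)
  m2$gap <- cbind(m2$gap, FALSE)
  m2$specs <- rbind(m2$specs, data.frame(char = n_char(pf$matrix) + 1L,
                                         max_state = 1L, ordered = FALSE,
                                         weight = 1))
  es2 <- ensemble_stats(m2, pf$tree)
  expect_equal(es2$S, es$S)
  expect_equal(es2$CI, es$CI)
  expect_equal(es2$RI, es$RI)
})

test_that("ensemble CI/RI agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  sim <- simulate_matrix(n_taxa = 7, n_char = 30, n_states = 3,
                         change_prob = 0.3, missing_frac = 0.1, seed = 8)
  m <- sim$matrix
  grid <- t(vapply(seq_len(n_taxa(m)), function(i) {
    vapply(seq_len(n_char(m)), function(j) {
      if (m$missing[i, j]) "?" else as.character(state_set(m, i, j)[1])
    }, character(1))
  }, character(n_char(m))))
  rownames(grid) <- m$taxa
  pd <- phangorn::phyDat(grid, type = "USER", levels = c("0", "1", "2"),
                         ambiguity = "?")
  es <- ensemble_stats(m, sim$tree)
  expect_equal(es$CI, phangorn::CI(sim$tree, pd), tolerance = 1e-10)
  expect_equal(es$RI, phangorn::RI(sim$tree, pd), tolerance = 1e-10)
})
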
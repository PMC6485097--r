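test_that("minimal NEXUS blocks parse into the expected state sets", {
  nx <- "#NEXUS
BEGIN DATA;
DIMENSIONS NTAX=2 NCHAR=1;
FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;
MATRIX
A 0
B 1
;
END;"
  m <- read_nexus(nx)
  expect_equal(n_taxa(m), 2L)
  expect_equal(n_char(m), 1L)
  expect_equal(state_set(m, "A", 1), 0L)
  expect_equal(state_set(m, "B", 1), 1L)
})

test_that("polymorphic, missing and gap tokens resolve correctly", {
  nx <- "#NEXUS
BEGIN DATA;
DIMENSIONS NTAX=2 NCHAR=3;
FORMAT SYMBOLS=\"012\" MISSING=? GAP=-;
MATRIX
A {01}2?
B 0-2
;
END;"
  m <- read_nexus(nx)
  expect_equal(state_set(m, "A", 1), c(0L, 1L))
  expect_false(m$missing[1, 1])
  # '?' resolves to the full observed range of its character
  expect_true(m$missing[1, 3])
  expect_equal(state_set(m, "A", 3), 0:2)
  # gap is missing for computation but remembered as gap
  expect_true(m$missing[2, 2])
  expect_true(m$gap[2, 2])
  expect_false(m$gap[1, 3])
})

test_that("NEXUS parsing is case-insensitive and whitespace-tolerant", {
  nx <- "#nexus
begin data;
  dimensions  ntax = 2  nchar = 2 ;
  format symbols=\"01\";
matrix
  'A  x' 0 1
  B      10
;
end;"
  m <- read_nexus(nx)
  expect_equal(m$taxa, c("A_x", "B"))   # quotes stripped, spaces collapsed
  expect_equal(state_set(m, "B", 1), 1L)
})

test_that("malformed NEXUS inputs raise informative errors", {
  base <- function(mat, ntax = 2) sprintf("#NEXUS
BEGIN DATA;
DIMENSIONS NTAX=%d NCHAR=2;
FORMAT SYMBOLS=\"01\";
MATRIX
%s
;
END;", ntax, mat)
  expect_error(read_nexus(base("A 01", ntax = 2)), "NTAX")
  expect_error(read_nexus(base("A 01\nA 10")), "duplicate taxon")
  expect_error(read_nexus(base("A 01\nB 0")), "expected 2")
  expect_error(read_nexus(base("A 01\nB 02")), "undeclared symbol")
})

test_that("TNT xread parses the minimal dialect and polymorphism", {
  m <- read_tnt("xread\n1 2\nA 0\nB 1\n;")
  expect_equal(n_taxa(m), 2L)
  expect_equal(state_set(m, "A", 1), 0L)
  m2 <- read_tnt("xread\n2 2\nA [01]0\nB 11\n;")
  expect_equal(state_set(m2, "A", 1), c(0L, 1L))
  expect_error(read_tnt("xread\n1 3\nA 0\nB 1\n;"), "ntax")
})

test_that("NEXUS and TNT writings of the same matrix read back identically", {
  for (seed in 1:5) {
    sim <- simulate_matrix(n_taxa = 10, n_char = 20, n_states = 3,
                           change_prob = 0.3, missing_frac = 0.1,
                           polymorphic_frac = 0.05, seed = seed)
    m <- sim$matrix
    m <- set_ordered(m, TRUE, chars = c(2L, 5L))
    m <- set_weights(m, 2, chars = 7L)
    mn <- read_nexus(write_nexus(m))
    mt <- read_tnt(write_tnt(m))
    expect_true(maxpars:::matrices_equal(m, mn))
    expect_true(maxpars:::matrices_equal(m, mt))
    expect_true(maxpars:::matrices_equal(mn, mt))
    # gap provenance round-trips too
    expect_identical(m$gap, mn$gap)
  }
})

test_that("writing an empty matrix is refused", {
  sim <- simulate_matrix(n_taxa = 4, n_char = 2, seed = 1)
  empty <- subset_matrix(sim$matrix, taxa = integer(0))
  expect_error(write_nexus(empty), "no taxa")
  expect_error(write_tnt(empty), "no taxa")
})

test_that("documented recodings replay as printed (polymorphism, state moves)", {
  grid <- rbind(
    Aetomylaeus = c("0", "1", "1"),
    Myliobatis  = c("1", "0", "1"),
    Rhinoptera  = c("1", "1", "2"),
    Gymnura     = c("0", "0", "0"))
  m <- char_matrix(grid)
  led <- recoding_ledger(
    taxon = c("Aetomylaeus", "Rhinoptera", "Myliobatis"),
    char = c(2L, 1L, 3L),
    old = c("1", "1", "*"),
    new = c("2", "0", "0/1"),
    note = c("ch. 27 analogue", "ch. 50 analogue", "ch. 16 analogue"))
  m2 <- apply_recodings(m, led)
  expect_equal(state_set(m2, "Aetomylaeus", 2), 2L)
  expect_equal(state_set(m2, "Rhinoptera", 1), 0L)
  expect_equal(state_set(m2, "Myliobatis", 3), c(0L, 1L))
  expect_equal(nrow(attr(m2, "diff")), 3L)
  # untouched cells identical
  expect_equal(state_set(m2, "Gymnura", 1), state_set(m, "Gymnura", 1))
})

test_that("recoding is idempotent and conflicts are reported", {
  m <- char_matrix(rbind(A = c("0", "1"), B = c("1", "0")))
  led <- recoding_ledger("A", 1, "0", "1", "x")
  m1 <- apply_recodings(m, led)
  m2 <- apply_recodings(m1, led)
  expect_true(maxpars:::matrices_equal(m1, m2))
  expect_equal(nrow(attr(m2, "diff")), 0L)
  bad <- recoding_ledger("B", 1, "0", "2", "x")   # B has state 1, not 0
  expect_error(apply_recodings(m, bad), "conflict.*found \\(1\\)")
  expect_error(apply_recodings(m, recoding_ledger("Z", 1, "0", "1")),
               "unknown taxon")
})

test_that("recoding changes exactly the listed cells", {
  sim <- simulate_matrix(n_taxa = 6, n_char = 10, n_states = 3,
                         change_prob = 0.4, seed = 3)
  m <- sim$matrix
  led <- recoding_ledger(c("t1", "t4"), c(3L, 7L), old = "*",
                         new = c("1", "0"))
  m2 <- apply_recodings(m, led)
  changed <- which(m2$bits != m$bits | m2$missing != m$missing)
  expect_lte(length(changed), 2L)
  expect_equal(m$specs$ordered, m2$specs$ordered)
  expect_equal(m$specs$weight, m2$specs$weight)
})

test_that("the shipped Promyliobatis ledger loads and is replayable", {
  led <- promyliobatis_recodings()
  expect_s3_class(led, "recoding_ledger")
  expect_true(all(c(9L, 16L, 27L, 30L, 50L, 63L) %in% led$char))
  expect_true(all(c("Aetomylaeus", "Myliobatis", "Rhinoptera", "Mobula",
                    "Weissobatis") %in% led$taxon))
  # replay on a synthetic matrix with the right shape: a stand-in for the
  # unavailable published matrix, binary cells everywhere
  taxa <- unique(led$taxon)
  grid <- matrix("1", length(taxa), 103,
                 dimnames = list(taxa, NULL))
  grid["Aetomylaeus", 9] <- "0"   # the one edit whose prior state is printed as 0
  m <- char_matrix(grid)
  m2 <- apply_recodings(m, led)
  expect_equal(state_set(m2, "Aetomylaeus", 27), 2L)
  expect_equal(state_set(m2, "Rhinoptera", 50), 0L)
  expect_equal(state_set(m2, "Myliobatis", 16), c(0L, 1L))
  # idempotent on re-application
  m3 <- apply_recodings(m2, led)
  expect_true(maxpars:::matrices_equal(m2, m3))
})
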
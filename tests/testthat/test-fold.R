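test_that("trivial folds behave", {
  f <- fold_mfe("AAAAAA")
  expect_equal(f$structure, "......")
  expect_equal(f$energy, 0)

  expect_equal(fold_mfe("GGGAAACCC")$structure, "(((...)))")
  expect_equal(enumerate_min_energy("ACGU")$structure, "....")
  expect_equal(enumerate_min_energy("ACGU")$energy, 0)
  expect_error(fold_mfe("ACGX"), "alphabet")
  expect_error(enumerate_min_energy(strrep("A", 19)), "18")
})

test_that("T and U are interchangeable and folding is deterministic", {
  a <- fold_mfe("GGGAAACCCGGGAAACCC")
  b <- fold_mfe("GGGAAACCCGGGAAACCC")
  expect_identical(a, b)
  expect_equal(fold_mfe("GGGTTTAAACCC")$energy, fold_mfe("GGGUUUAAACCC")$energy)
})

test_that("fold_mfe matches the exhaustive oracle on random short sequences", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(6:14, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    expect_equal(fold_mfe(s)$energy, enumerate_min_energy(s)$energy,
                 tolerance = 1e-9, label = s)
  }
})

test_that("any returned structure with pairs has energy <= 0", {
  set.seed(3)
  for (i in 1:30) {
    s <- random_dna(sample(20:60, 1), gc = 0.6)
    f <- fold_mfe(s)
    if (grepl("(", f$structure, fixed = TRUE)) expect_lte(f$energy, 0)
    if (!grepl("(", f$structure, fixed = TRUE)) expect_equal(f$energy, 0)
    # brackets balanced and partner is an involution
    expect_equal(sum(strsplit(f$structure, "")[[1]] == "("),
                 sum(strsplit(f$structure, "")[[1]] == ")"))
    p <- f$partner
    paired <- which(p > 0)
    expect_true(all(p[p[paired]] == paired))
  }
})

test_that("constrained folding forces positions open and never lowers energy", {
  s <- "GGGAAACCC"
  whole <- fold_constrained(s, c(1, 9))
  expect_equal(whole$structure, ".........")
  expect_equal(whole$energy, 0)
  expect_equal(fold_constrained(s)$energy, fold_mfe(s)$energy)
  expect_error(fold_constrained(s, c(0, 3)), "out of bounds")

  set.seed(17)
  for (i in 1:40) {
    s <- random_dna(40, gc = 0.6)
    st <- sample(1:30, 1)
    con <- fold_constrained(s, c(st, st + 9))
    expect_gte(con$energy, fold_mfe(s)$energy - 1e-9)
    expect_true(all(con$partner[st:(st + 9)] == 0))
  }
})

test_that("duplex energy matches the independent oracle and is monotone", {
  a <- "GGAUCGAUCGAUCGAUCGAUC"
  b <- revcomp(a)
  perfect <- duplex_energy(a, b)
  bch <- strsplit(b, "")[[1]]
  bch[9:12] <- c("A", "A", "A", "A")  # 4 central mismatches
  worse <- duplex_energy(a, paste(bch, collapse = ""))
  expect_lt(perfect, worse)

  expect_equal(duplex_energy("AAAA", "CCCC"), 0)

  set.seed(33)
  for (i in 1:25) {
    x <- paste(sample(c("A", "C", "G", "U"), sample(4:10, 1), TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "U"), sample(4:10, 1), TRUE), collapse = "")
    expect_equal(duplex_energy(x, y), smrnakit:::duplex_energy_oracle(x, y),
                 tolerance = 1e-9, label = paste(x, y))
  }
})

test_that("the energy table's symmetric entries are reverse-complement invariant", {
  # additive pair stabilities make stack(p over q) == stack(rev q over rev p)
  # exactly; whole-fold energies are therefore equal under reverse
  # complementation whenever no G:U wobble can form (a G:U pair maps to the
  # unpairable C:A). Assert on wobble-free alphabets.
  set.seed(44)
  for (i in 1:15) {
    gc_only <- paste(sample(c("G", "C"), sample(12:30, 1), TRUE,
                            prob = c(0.5, 0.5)), collapse = "")
    expect_equal(fold_mfe(gc_only)$energy, fold_mfe(revcomp(gc_only))$energy,
                 tolerance = 1e-9, label = gc_only)
    au_only <- paste(sample(c("A", "T"), sample(12:30, 1), TRUE), collapse = "")
    expect_equal(fold_mfe(au_only)$energy, fold_mfe(revcomp(au_only))$energy,
                 tolerance = 1e-9, label = au_only)
  }
  # stack symmetry asserted directly on the scorer
  e1 <- structure_energy("GGGAAACCC", rbind(c(1, 9), c(2, 8), c(3, 7)))
  e2 <- structure_energy(revcomp("GGGAAACCC"), rbind(c(1, 9), c(2, 8), c(3, 7)))
  expect_equal(e1, e2)
})

test_that("adding G:C stacks never raises the MFE", {
  base <- "GGGGAAAACCCC"
  grown <- "GGGGGGAAAACCCCCC"
  expect_lte(fold_mfe(grown)$energy, fold_mfe(base)$energy)
  expect_lte(fold_mfe("GGGGAAACCCC")$energy, fold_mfe("GGGAAACCC")$energy)
})
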
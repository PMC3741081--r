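test_that("base complementarity covers exactly the three pair types", {
  expect_true(complementary("A", "U"))
  expect_true(complementary("U", "A"))
  expect_true(complementary("C", "G"))
  expect_true(complementary("G", "U"))
  expect_false(complementary("A", "C"))
  expect_false(complementary("A", "G"))
  expect_false(complementary("U", "U"))
  expect_error(complementary("A", "X"), "RNA bases")
})

test_that("sequence normalization folds case, maps T to U, rejects junk", {
  expect_equal(normalize_rna("acgu"), "ACGU")
  expect_equal(normalize_rna("ACGT"), "ACGU")
  expect_error(normalize_rna("ACGN"), "non-RNA")
})

test_that("maximum pairing handles base cases and the nine-base example", {
  expect_equal(fold_max_pairs(""), 0)
  expect_equal(fold_max_pairs("A"), 0)
  expect_equal(fold_max_pairs("AA"), 0)
  expect_equal(fold_max_pairs("AU"), 1)
  expect_equal(fold_max_pairs("ACAGUGACU"), 3)
  expect_equal(fold_max_pairs("ACAGUGACU"), brute_max_pairs("ACAGUGACU"))
})

test_that("traceback returns a nested folding scoring the matrix optimum", {
  f <- traceback_max_pairs("AU")
  expect_equal(f$pairs, matrix(c(0L, 1L), 1))
  expect_equal(nrow(traceback_max_pairs("AA")$pairs), 0L)
  set.seed(401)
  for (rep in 1:25) {
    s <- rand_rna(sample(2:28, 1))
    f <- traceback_max_pairs(s)
    expect_true(is_nested(f))
    expect_equal(count_complementary_pairs(f, s), fold_max_pairs(s))
  }
})

test_that("folding objects enforce nestedness", {
  expect_error(folding(rbind(c(0L, 2L), c(1L, 3L)), 4), "crossing")
  expect_true(is_nested(folding(rbind(c(0L, 3L), c(1L, 2L)), 4)))
})

test_that("partition function matches enumeration and its invariants", {
  expect_equal(partition_function("AU")$Z, 1 + exp(1))
  b <- partition_function("GGG")  # no complementary pair anywhere
  expect_equal(b$Z, 1)
  set.seed(402)
  for (rep in 1:20) {
    s <- rand_rna(sample(1:12, 1))
    z <- partition_function(s)$Z
    expect_gte(z, 1)
    expect_true(rel_close(z, brute_partition(s), 1e-9))
    # appending a pairable base never decreases Z
    z2 <- partition_function(paste0(s, "A"))$Z
    z3 <- partition_function(paste0(s, "A", "U"))$Z
    expect_gte(z3, z2)
  }
  # inside base cases
  B <- partition_function("ACGU")
  for (i in 1:5) expect_equal(B$beta2[i, i], 1)
})

test_that("base-pair probabilities match enumeration and are coherent", {
  expect_equal(base_pair_probabilities("AU")$P[1, 2], exp(1) / (1 + exp(1)))
  set.seed(403)
  for (rep in 1:15) {
    n <- sample(2:10, 1)
    s <- rand_rna(n)
    res <- base_pair_probabilities(s)
    expect_true(max(abs(res$P - brute_bpp(s))) <= 1e-9)
    expect_true(all(res$P >= 0 & res$P <= 1 + 1e-12))
    expect_true(all(rowSums(res$P) <= 1 + 1e-12))  # a base pairs at most once
    expect_true(all(res$gamma <= res$Z * (1 + 1e-12)))
  }
})

test_that("CFG recognition matches derivation search on fixed and random cases", {
  g <- parse_grammar(c("S -> A B", "A -> 'a'", "B -> 'b'"))
  expect_true(cfg_recognize(g, c("a", "b"))$accepted)
  expect_false(cfg_recognize(g, c("b", "a"))$accepted)
  expect_false(cfg_recognize(g, "a")$accepted)  # no unit rule S -> a
  expect_false(cfg_recognize(g, character(0))$accepted)
  set.seed(404)
  for (rep in 1:40) {
    g <- gen_random_cnf(sample(2:5, 1), sample(2:10, 1))
    toks <- rand_sentence(sample(1:8, 1))
    expect_equal(cfg_recognize(g, toks, cutoff = 4L)$accepted,
                 brute_cfg(g, toks))
  }
})

test_that("WCFG best parse sums all rule applications, -Inf if unparseable", {
  g <- parse_grammar(c("S -> A B 1", "A -> 'a' 2", "B -> 'b' 3"))
  expect_equal(wcfg_best_parse(g, c("a", "b")), 6)
  expect_equal(wcfg_best_parse(g, "b"), -Inf)
  set.seed(405)
  for (rep in 1:40) {
    g <- gen_random_cnf(sample(2:5, 1), sample(2:10, 1))
    toks <- rand_sentence(sample(1:8, 1))
    expect_equal(wcfg_best_parse(g, toks, cutoff = 4L), brute_wcfg(g, toks))
  }
})

test_that("a seventeen-column pair set validates as a nested folding", {
  f <- folding(rbind(c(1L, 4L), c(7L, 15L), c(9L, 12L)), 17)
  expect_true(is_nested(f))
})

test_that("alignment-with-folding agrees with the lattice recursion oracle", {
  set.seed(406)
  for (rep in 1:10) {
    S <- gen_random_multistring(sample(1:5, 2, replace = TRUE))
    sc <- saf_scoring()
    expect_equal(saf_score(S, sc, cutoff = 4L), brute_saf(S, sc))
  }
})

test_that("alignment-with-folding is symmetric for order-symmetric scoring", {
  set.seed(407)
  for (rep in 1:6) {
    ss <- c(rand_rna(sample(1:4, 1)), rand_rna(sample(1:4, 1)))
    sc <- saf_scoring()  # rho and tau are symmetric in the string order
    a <- saf_score(multistring_instance(ss), sc)
    b <- saf_score(multistring_instance(rev(ss)), sc)
    expect_equal(a, b)
  }
})
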
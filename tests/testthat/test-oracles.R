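str_rev <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")

test_that("folding enumeration produces each nested folding exactly once", {
  fs <- enumerate_foldings("AU")
  expect_length(fs, 2)                          # empty and {0*1}
  expect_length(enumerate_foldings("AA"), 1)    # empty only
  expect_length(enumerate_foldings("AAAA"), 1)  # n identical unpairable bases
  keys <- vapply(enumerate_foldings("GCAUGC"),
                 function(f) paste(t(f$pairs), collapse = ","), character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("folding counts are invariant under sequence reversal", {
  # complementarity is symmetric and nesting is mirror-invariant, so the
  # folding set of the reversed string is the mirror image of the original
  # (note: reversal PLUS complementation is not a symmetry here — the
  # wobble pair G.U maps to C.A, which cannot pair)
  set.seed(501)
  for (rep in 1:10) {
    s <- rand_rna(sample(2:9, 1))
    expect_length(enumerate_foldings(str_rev(s)),
                  length(enumerate_foldings(s)))
  }
})

test_that("oracle guards are hard errors, not silent truncation", {
  long <- paste(rep("AU", 10), collapse = "")
  expect_error(enumerate_foldings(long), "guard")
  expect_error(brute_cfg(gen_random_cnf(2, 2, seed = 1), rep("a", 25)), "guard")
  expect_error(brute_saf(multistring_instance(c("ACGUACGUAC", "ACGUACGUAC")),
                         saf_scoring(), max_cells = 50), "guard")
})

test_that("naive CKY handles single tokens via terminal rules only", {
  g <- parse_grammar(c("S -> A A", "S -> 'a' 5", "A -> 'a' 1"))
  expect_true(brute_cfg(g, "a"))
  expect_equal(brute_wcfg(g, "a"), 5)
  expect_equal(brute_wcfg(g, c("b")), -Inf)
})

test_that("the brute lattice recursion matches the single-string oracle", {
  set.seed(502)
  for (rep in 1:10) {
    s <- rand_rna(sample(1:8, 1))
    expect_equal(brute_saf(multistring_instance(s), saf_scoring_fold()),
                 brute_max_pairs(s))
  }
  expect_equal(brute_saf(multistring_instance(c("", "")), saf_scoring()), 0)
})
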
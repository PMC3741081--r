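test_that("the two-base worked example matches enumeration", {
  # "AU" has exactly two foldings: empty (weight 1) and the pair (weight e)
  res <- base_pair_probabilities("AU")
  expect_equal(res$outside$alpha4[2, 3], 1)           # alpha4[1,2] = beta2[0,1]
  expect_equal(res$gamma[1, 3], exp(1))               # gamma[0,2] = e
  expect_equal(res$P[1, 2], exp(1) / (1 + exp(1)))
  expect_equal(res$outside$alpha4[1, 3], 1)           # empty residual
})

test_that("outside engine equals the classical outside evaluator", {
  set.seed(201)
  v <- standard_variants()$dot
  for (rep in 1:25) {
    n <- sample(1:36, 1)
    s <- rand_rna(n)
    inside <- run_inside(n + 1L, partition_spec(s))
    sp <- bpp_spec(s)
    eng <- run_outside(inside, sp, cutoff = sample(c(2L, 8L, 32L), 1))
    cls <- run_outside_classical(inside, sp)
    for (k in 1:4) mats_equal(eng[[k]], cls[[k]], v, 1e-9)
  }
})

test_that("outside results are invariant to the recursion cutoff", {
  set.seed(202)
  v <- standard_variants()$dot
  for (rep in 1:5) {
    s <- rand_rna(sample(8:30, 1))
    inside <- run_inside(nchar(s) + 1L, partition_spec(s))
    sp <- bpp_spec(s)
    runs <- lapply(c(1L, 2L, 8L, 32L),
                   function(co) run_outside(inside, sp, cutoff = co))
    for (r in runs[-1]) for (k in 1:4) mats_equal(r[[k]], runs[[1]][[k]], v, 1e-12)
  }
})

test_that("prefix-form bridging equals its naive per-cell sum (transposition)", {
  set.seed(203)
  s <- rand_rna(14)
  n <- nchar(s)
  inside <- run_inside(n + 1L, partition_spec(s))
  out <- run_outside(inside, bpp_spec(s))
  # alpha2[i,j] = sum_{q in [0,i)} beta2[q,i] * alpha1[q,j], by definition
  for (i in 0:n) for (j in i:n) {
    if (j == n) next
    want <- 0
    if (i >= 1) for (q in 0:(i - 1)) {
      want <- want + inside$beta2[q + 1, i + 1] * out$alpha1[q + 1, j + 1]
    }
    expect_true(rel_close(out$alpha2[i + 1, j + 1], want, 1e-9))
  }
})

test_that("suffix-form values equal their naive per-cell sum", {
  set.seed(204)
  s <- rand_rna(12)
  n <- nchar(s)
  inside <- run_inside(n + 1L, partition_spec(s))
  out <- run_outside(inside, bpp_spec(s))
  for (i in 0:n) for (j in i:n) {
    if (j == n) next
    want <- 0
    if (j + 1 <= n) for (q in (j + 1):n) {
      want <- want + out$alpha4[i + 1, q + 1] * inside$beta1[j + 1, q + 1]
    }
    expect_true(rel_close(out$alpha3[i + 1, j + 1], want, 1e-9))
  }
})

test_that("invalid outside cells stay phi and boundaries read as phi", {
  s <- rand_rna(10)
  inside <- run_inside(11L, partition_spec(s))
  out <- run_outside(inside, bpp_spec(s))
  for (k in 1:4) expect_true(all(out[[k]][lower.tri(out[[k]])] == 0))
  # right-boundary cells: residual is the prefix alone
  for (i in 0:10) expect_equal(out$alpha4[i + 1, 11], inside$beta2[1, i + 1])
})

test_that("outside debug mode validates the pre-condition", {
  s <- "GCAUGCA"
  inside <- run_inside(8L, partition_spec(s))
  expect_silent({
    out <- run_outside(inside, bpp_spec(s), cutoff = 2L, verify = TRUE)
  })
  expect_equal(out$alpha4[1, 8], 1)
})

test_that("a missing or malformed inside set is a dependency error", {
  expect_error(run_outside(list(), bpp_spec("ACGU")), "inside")
  expect_error(run_outside(list(matrix(0, 2, 2), matrix(0, 3, 3)),
                           bpp_spec("A")), "equal size")
})
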
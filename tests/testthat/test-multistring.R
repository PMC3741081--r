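test_that("codec encodes mixed-radix with string 0 least significant", {
  cd <- position_codec(c(3, 3))
  expect_equal(codec_encode(c(0, 0), cd), 0L)
  expect_equal(codec_encode(c(1, 2), cd), 9L)           # 1 + 2*4
  expect_equal(codec_encode(c(3, 3), cd), 15L)          # last position
  expect_error(codec_encode(c(4, 0), cd), "out of range")
})

test_that("codec round-trips on every index of small lattices", {
  for (lens in list(c(4L), c(3L, 2L), c(2L, 3L, 1L), c(0L, 2L))) {
    cd <- position_codec(lens)
    for (i in 0:(cd$size - 1L)) {
      X <- codec_decode(i, cd)
      expect_equal(codec_encode(X, cd), i)
    }
  }
})

test_that("componentwise order is monotone under encoding but not conversely", {
  cd <- position_codec(c(3, 3))
  # exhaustive monotonicity m <= 3, n <= 4
  for (lens in list(c(4L, 4L), c(3L, 2L, 4L))) {
    cdl <- position_codec(lens)
    for (i in 0:(cdl$size - 1L)) for (j in 0:(cdl$size - 1L)) {
      if (position_leq(codec_decode(i, cdl), codec_decode(j, cdl))) {
        expect_lte(i, j)
      }
    }
  }
  # h(X) <= h(Y) does not imply X <= Y
  expect_equal(codec_decode(3L, cd), c(3L, 0L))
  expect_equal(codec_decode(4L, cd), c(0L, 1L))
  expect_false(position_leq(c(3L, 0L), c(0L, 1L)))
  expect_true(position_leq(c(1L, 1L), c(2L, 1L)))
  expect_true(position_leq(c(2L, 2L), c(2L, 2L)))
  expect_error(position_leq(c(1L, 1L), c(1L, 1L, 1L)), "arity")
})

test_that("local increments and decrements enumerate clipped 0/1 moves", {
  cd <- position_codec(c(3, 3))
  inc <- local_increments(c(0L, 0L), cd)
  expect_setequal(lapply(inc, as.integer),
                  list(c(1L, 0L), c(0L, 1L), c(1L, 1L)))
  expect_length(local_increments(c(3L, 3L), cd), 0)     # last position
  cd1 <- position_codec(3L)
  expect_equal(local_increments(2L, cd1), list(3L))
  dec <- local_decrements(c(1L, 1L), cd)
  expect_setequal(lapply(dec, as.integer),
                  list(c(0L, 1L), c(1L, 0L), c(0L, 0L)))
})

test_that("with one string the lattice reduction is the plain inside run", {
  set.seed(301)
  for (rep in 1:10) {
    s <- rand_rna(sample(1:12, 1))
    S <- multistring_instance(s)
    sp <- saf_spec(S, saf_scoring_fold())
    B1 <- run_multistring_inside(S, sp, cutoff = 4L)
    expect_equal(B1$beta[1, nchar(s) + 1L], fold_max_pairs(s))
  }
})

test_that("cells with incomparable decoded endpoints hold phi", {
  S <- multistring_instance(c("AU", "GC"))
  cd <- position_codec(S$lengths)
  B <- run_multistring_inside(S, saf_spec(S, saf_scoring()), cutoff = 2L)$beta
  for (i in 0:(cd$size - 1L)) for (j in 0:(cd$size - 1L)) {
    if (!position_leq(codec_decode(i, cd), codec_decode(j, cd))) {
      expect_equal(B[i + 1L, j + 1L], -Inf)
    }
  }
})

test_that("masked split points contribute phi terms (reduction correctness)", {
  # for every q in (i, j) whose decoded position is not between the decoded
  # endpoints, at least one factor of the split product is phi
  S <- multistring_instance(c("ACGU", "GAUC"))
  cd <- position_codec(S$lengths)
  B <- run_multistring_inside(S, saf_spec(S, saf_scoring()), cutoff = 8L)$beta
  for (i in 0:(cd$size - 1L)) for (j in 0:(cd$size - 1L)) {
    X <- codec_decode(i, cd); Y <- codec_decode(j, cd)
    if (!position_leq(X, Y) || j - i < 2L) next
    for (q in (i + 1L):(j - 1L)) {
      Q <- codec_decode(q, cd)
      if (position_leq(X, Q) && position_leq(Q, Y)) {
        expect_true(i < q && q < j)   # h maps (X, Y) into (i, j)
      } else {
        expect_true(B[i + 1L, q + 1L] == -Inf || B[q + 1L, j + 1L] == -Inf)
      }
    }
  }
})

test_that("the multistring reduction rejects non-commutative aggregation", {
  weird <- mult_variant("left_fold2", "real", `+`, function(a, b) a, -Inf,
                        oplus_commutative = FALSE)
  sp <- inside_spec(1L, weird, list(list(c(1L, 1L))),
                    function(i, j, mu, read) 0)
  expect_error(run_multistring_inside(multistring_instance("AC"), sp),
               "commutative")
})

test_that("the lattice memory cap is enforced", {
  S <- multistring_instance(c("ACGUACGUA", "ACGUACGUA"))
  expect_error(run_multistring_inside(S, saf_spec(S, saf_scoring()),
                                      max_size = 50L), "memory cap")
})

test_that("empty strings give degenerate radix-1 lattices", {
  S <- multistring_instance(c("", "AU"))
  expect_equal(position_codec(S$lengths)$size, 3)
  sc <- saf_score(S, saf_scoring())
  expect_equal(sc, brute_saf(S, saf_scoring()))
})
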
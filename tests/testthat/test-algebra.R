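sv <- standard_variants()

test_that("standard variants have the right operators and zero elements", {
  expect_equal(sv$dot$otimes(3, 4), 12)
  expect_equal(sv$dot$oplus(3, 0), 3)           # phi neutral
  expect_equal(sv$max_plus$otimes(5, sv$max_plus$phi), -Inf)  # phi absorbs
  expect_equal(sv$min_plus$phi, Inf)
  expect_true(sv$boolean$oplus(TRUE, FALSE))
  expect_false(sv$boolean$otimes(TRUE, FALSE))
  for (v in sv) expect_true(v$oplus_commutative)
})

test_that("oplus associativity and phi laws hold on sampled triples", {
  set.seed(41)
  for (v in sv) {
    for (rep in 1:50) {
      abc <- if (v$domain == "boolean") sample(c(TRUE, FALSE), 3, replace = TRUE)
             else sample(-9:9, 3, replace = TRUE)
      a <- abc[1]; b <- abc[2]; cc <- abc[3]
      expect_equal(v$oplus(v$oplus(a, b), cc), v$oplus(a, v$oplus(b, cc)))
      expect_equal(v$oplus(a, v$phi), a)
      expect_equal(v$oplus(v$phi, a), a)
      expect_equal(v$otimes(a, v$phi), v$phi)
      expect_equal(v$otimes(v$phi, a), v$phi)
    }
  }
})

test_that("mat_mult obeys the fold contract, empty inner dimension, identity", {
  # empty inner dimension: all-phi result
  for (v in sv) {
    Z <- mat_mult(phi_matrix(v, 2, 0), phi_matrix(v, 0, 3), v)
    expect_equal(dim(Z), c(2L, 3L))
    expect_true(all(Z == v$phi))
  }
  # dot identity
  Y <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(mat_mult(diag(2), Y, sv$dot), Y)
  # frozen max-plus example (naive triple-loop value)
  X <- matrix(c(1, 3, 2, 4), 2)  # [[1,2],[3,4]] row-wise
  Y <- matrix(c(5, 7, 6, 8), 2)
  expect_equal(mat_mult(X, Y, sv$max_plus),
               matrix(c(9, 11, 10, 12), 2))
  expect_error(mat_mult(matrix(0, 2, 3), matrix(0, 2, 3), sv$dot),
               "dimension mismatch")
})

test_that("mat_add is entrywise oplus with shape checking", {
  expect_equal(mat_add(matrix(c(1, 2), 1), matrix(c(3, 4), 1), sv$dot),
               matrix(c(4, 6), 1))
  expect_equal(mat_add(matrix(1), matrix(2), sv$max_plus), matrix(2))
  X <- matrix(c(5, -2, 0, 7), 2)
  expect_equal(mat_add(X, phi_matrix(sv$max_plus, 2, 2), sv$max_plus), X)
  expect_error(mat_add(matrix(0, 2, 2), matrix(0, 3, 2), sv$dot), "shape")
})

test_that("block concatenation identities hold on seeded random blocks", {
  set.seed(42)
  for (v in sv) {
    tol <- if (v$name == "dot") 1e-12 else 0
    for (rep in 1:100) {
      n <- sample(1:6, 1)
      X1 <- rand_matrix(n, n, v); X2 <- rand_matrix(n, n, v)
      Y <- rand_matrix(n, n, v)
      Y1 <- rand_matrix(n, n, v); Y2 <- rand_matrix(n, n, v)
      expect_true(check_block_identities(X1, X2, Y, Y1, Y2, v, tol = max(tol, 1e-12)))
    }
    # all-phi blocks
    P <- phi_matrix(v, 3, 3)
    expect_true(check_block_identities(P, P, P, P, P, v))
  }
})

test_that("multiplying by an all-phi matrix yields all-phi", {
  set.seed(43)
  for (v in sv) {
    X <- rand_matrix(4, 4, v)
    Z <- mat_mult(X, phi_matrix(v, 4, 4), v)
    expect_true(all(Z == v$phi))
    Z2 <- mat_mult(phi_matrix(v, 4, 4), X, v)
    expect_true(all(Z2 == v$phi))
  }
})

test_that("registered kernels agree with the naive kernel on random pairs", {
  set.seed(44)
  for (v in sv) {
    for (kern in setdiff(list_kernels(v), "naive")) {
      for (rep in 1:25) {
        n1 <- sample(1:48, 1); n2 <- sample(0:48, 1); n3 <- sample(1:48, 1)
        X <- rand_matrix(n1, n2, v); Y <- rand_matrix(n2, n3, v)
        A <- mat_mult(X, Y, v, kern)
        B <- mat_mult(X, Y, v, "naive")
        tol <- if (v$name == "dot") 1e-9 else 0
        expect_true(matrices_close(A, B, v, max(tol, 1e-12)),
                    label = paste(v$name, kern, "agrees with naive"))
      }
    }
  }
})

test_that("kernel registry enforces the commutativity capability", {
  weird <- mult_variant("left_fold", "real", `*`, function(a, b) a + 2 * b, 0,
                        oplus_commutative = FALSE)
  expect_error(register_kernel(weird, function(X, Y) X, "reordering",
                               reorders = TRUE),
               "non-commutative")
  # order-preserving kernels are fine
  expect_silent(register_kernel(weird, naive_kernel(weird), "naive"))
  expect_true("naive" %in% list_kernels(weird))
})

test_that("the operation counter reflects Strassen's savings", {
  set.seed(45)
  X <- matrix(runif(96 * 96), 96)
  Y <- matrix(runif(96 * 96), 96)
  reset_mult_op_count()
  invisible(mat_mult(X, Y, sv$dot, "default"))
  dense <- mult_op_count()
  reset_mult_op_count()
  invisible(mat_mult(X, Y, sv$dot, "strassen"))
  strassen <- mult_op_count()
  expect_equal(dense, 96^3)
  expect_lt(strassen, dense)
})
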
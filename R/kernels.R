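# Kernel registry and shipped multiplication kernels.
#
# A kernel is a function (X, Y) -> Z obeying the mat_mult contract for one
# variant.  Kernels that claim reordered accumulation are rejected for
# variants whose oplus is not commutative (the naive kernel folds strictly
# in increasing inner index).  A global counter tracks the number of scalar
# otimes operations a naive evaluation of each performed product would cost,
# which makes sub-cubic kernels measurable.

.valiantdp_state <- new.env(parent = emptyenv())
.valiantdp_state$kernels <- list()
.valiantdp_state$op_count <- 0

.count_ops <- function(n) {
  .valiantdp_state$op_count <- .valiantdp_state$op_count + n
  invisible(NULL)
}

#' Scalar multiplication counter
#'
#' Every kernel charges the number of scalar `otimes` operations it performs
#' (for dense kernels `n1*n2*n3` per product; for the Strassen kernel only
#' the leaf products are charged, so genuinely fewer operations are counted).
#' `reset_mult_op_count()` zeroes the counter, `mult_op_count()` reads it.
#'
#' @return `mult_op_count()` returns the current count as a double.
#' @export
mult_op_count <- function() .valiantdp_state$op_count

#' @rdname mult_op_count
#' @export
reset_mult_op_count <- function() {
  .valiantdp_state$op_count <- 0
  invisible(NULL)
}

#' Register a multiplication kernel for a variant
#'
#' @param v a [mult_variant].
#' @param kernel function `(X, Y) -> Z` obeying the [mat_mult()] contract for
#'   `v`.
#' @param name kernel identifier used by `mat_mult(..., kernel = name)`.
#' @param reorders does the kernel accumulate in an order other than
#'   increasing inner index?  Such kernels are rejected unless the variant's
#'   `oplus` is commutative.
#' @export
register_kernel <- function(v, kernel, name, reorders = FALSE) {
  stopifnot(inherits(v, "mult_variant"), is.function(kernel),
            is.character(name), length(name) == 1L)
  if (reorders && !v$oplus_commutative) {
    stop("kernel '", name, "' reorders accumulation but variant '", v$name,
         "' has a non-commutative oplus", call. = FALSE)
  }
  key <- paste0(v$name, "/", name)
  .valiantdp_state$kernels[[key]] <- kernel
  invisible(NULL)
}

#' @rdname register_kernel
#' @return `list_kernels` returns the kernel names registered for the variant.
#' @export
list_kernels <- function(v) {
  keys <- names(.valiantdp_state$kernels)
  pre <- paste0(v$name, "/")
  sub(pre, "", keys[startsWith(keys, pre)], fixed = TRUE)
}

get_kernel <- function(v, name = "default") {
  key <- paste0(v$name, "/", name)
  fn <- .valiantdp_state$kernels[[key]]
  if (is.null(fn)) {
    stop("no kernel '", name, "' registered for variant '", v$name, "'",
         call. = FALSE)
  }
  fn
}

#' Naive reference kernel
#'
#' Triple loop over the variant's scalar operators, folding the inner index
#' strictly left to right.  Correct for any variant (including hypothetical
#' non-commutative `oplus`); used as the agreement oracle for every other
#' kernel.
#'
#' @param v a [mult_variant].
#' @return a kernel function `(X, Y) -> Z`.
#' @export
naive_kernel <- function(v) {
  force(v)
  function(X, Y) {
    n1 <- nrow(X); n2 <- ncol(X); n3 <- ncol(Y)
    Z <- phi_matrix(v, n1, n3)
    if (n2 == 0L) return(Z)
    .count_ops(as.double(n1) * n2 * n3)
    for (i in seq_len(n1)) {
      for (j in seq_len(n3)) {
        acc <- v$otimes(X[[i, 1L]], Y[[1L, j]])
        if (n2 > 1L) for (q in 2:n2) acc <- v$oplus(acc, v$otimes(X[[i, q]], Y[[q, j]]))
        Z[i, j] <- acc
      }
    }
    Z
  }
}

# dense vectorized kernels ----------------------------------------------

.dot_kernel <- function(X, Y) {
  n2 <- ncol(X)
  if (n2 == 0L) return(matrix(0, nrow(X), ncol(Y)))
  .count_ops(as.double(nrow(X)) * n2 * ncol(Y))
  X %*% Y
}

.boolean_kernel <- function(X, Y) {
  n2 <- ncol(X)
  if (n2 == 0L) return(matrix(FALSE, nrow(X), ncol(Y)))
  .count_ops(as.double(nrow(X)) * n2 * ncol(Y))
  ((X + 0) %*% (Y + 0)) > 0
}

# Tropical product: one vectorized rank-1 update per inner index.  The
# theoretically sub-cubic min-plus algorithms are out of scope; this is the
# practical dense kernel.
.tropical_kernel <- function(take_max) {
  ext <- function(a, b) if (take_max) pmax(a, b) else pmin(a, b)
  phi <- if (take_max) -Inf else Inf
  function(X, Y) {
    n1 <- nrow(X); n2 <- ncol(X); n3 <- ncol(Y)
    Z <- matrix(phi, n1, n3)
    if (n2 == 0L) return(Z)
    .count_ops(as.double(n1) * n2 * n3)
    for (q in seq_len(n2)) {
      Z <- ext(Z, outer(X[, q], Y[q, ], `+`))
    }
    Z
  }
}

# Strassen ---------------------------------------------------------------

.strassen_rec <- function(X, Y, threshold) {
  n1 <- nrow(X); n2 <- ncol(X); n3 <- ncol(Y)
  if (max(n1, n2, n3) <= threshold || min(n1, n2, n3) < 2L) {
    .count_ops(as.double(n1) * n2 * n3)
    return(X %*% Y)
  }
  # pad every dimension up to even, split into quadrants
  m1 <- n1 + n1 %% 2L; m2 <- n2 + n2 %% 2L; m3 <- n3 + n3 %% 2L
  if (m1 != n1 || m2 != n2) {
    Xp <- matrix(0, m1, m2); Xp[seq_len(n1), seq_len(n2)] <- X; X <- Xp
  }
  if (m2 != n2 || m3 != n3) {
    Yp <- matrix(0, m2, m3); Yp[seq_len(n2), seq_len(n3)] <- Y; Y <- Yp
  }
  h1 <- m1 %/% 2L; h2 <- m2 %/% 2L; h3 <- m3 %/% 2L
  i1 <- seq_len(h1); i2 <- h1 + i1
  q1 <- seq_len(h2); q2 <- h2 + q1
  j1 <- seq_len(h3); j2 <- h3 + j1
  A11 <- X[i1, q1, drop = FALSE]; A12 <- X[i1, q2, drop = FALSE]
  A21 <- X[i2, q1, drop = FALSE]; A22 <- X[i2, q2, drop = FALSE]
  B11 <- Y[q1, j1, drop = FALSE]; B12 <- Y[q1, j2, drop = FALSE]
  B21 <- Y[q2, j1, drop = FALSE]; B22 <- Y[q2, j2, drop = FALSE]
  M1 <- .strassen_rec(A11 + A22, B11 + B22, threshold)
  M2 <- .strassen_rec(A21 + A22, B11, threshold)
  M3 <- .strassen_rec(A11, B12 - B22, threshold)
  M4 <- .strassen_rec(A22, B21 - B11, threshold)
  M5 <- .strassen_rec(A11 + A12, B22, threshold)
  M6 <- .strassen_rec(A21 - A11, B11 + B12, threshold)
  M7 <- .strassen_rec(A12 - A22, B21 + B22, threshold)
  Z <- matrix(0, m1, m3)
  Z[i1, j1] <- M1 + M4 - M5 + M7
  Z[i1, j2] <- M3 + M5
  Z[i2, j1] <- M2 + M4
  Z[i2, j2] <- M1 - M2 + M3 + M6
  Z[seq_len(n1), seq_len(n3), drop = FALSE]
}

#' Strassen-style recursive kernel
#'
#' Recursive seven-product multiplication for the dot (and, via a 0/1
#' integer product with thresholding, boolean) variant.  Matrices whose
#' largest dimension is at most `threshold` fall back to a dense product.
#' Each leaf product charges its naive scalar-multiplication cost to the
#' operation counter, so the counter reflects the genuinely sub-cubic number
#' of scalar multiplications the recursion performs.
#'
#' @param threshold side length below which the dense product is used.
#' @param boolean if `TRUE`, inputs are logical and the numeric result is
#'   thresholded at `> 0` (exact over the boolean semiring).
#' @return a kernel function `(X, Y) -> Z`.
#' @export
strassen_kernel <- function(threshold = 32L, boolean = FALSE) {
  force(threshold)
  function(X, Y) {
    if (ncol(X) == 0L) {
      return(if (boolean) matrix(FALSE, nrow(X), ncol(Y))
             else matrix(0, nrow(X), ncol(Y)))
    }
    if (boolean) {
      .strassen_rec(X + 0, Y + 0, threshold) > 0
    } else {
      .strassen_rec(X, Y, threshold)
    }
  }
}

.register_default_kernels <- function() {
  sv <- standard_variants()
  for (v in sv) register_kernel(v, naive_kernel(v), "naive")
  register_kernel(sv$dot, .dot_kernel, "default")
  register_kernel(sv$boolean, .boolean_kernel, "default")
  register_kernel(sv$max_plus, .tropical_kernel(TRUE), "default")
  register_kernel(sv$min_plus, .tropical_kernel(FALSE), "default")
  register_kernel(sv$dot, strassen_kernel(), "strassen", reorders = TRUE)
  register_kernel(sv$boolean, strassen_kernel(boolean = TRUE), "strassen",
                  reorders = TRUE)
  invisible(NULL)
}
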
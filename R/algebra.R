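#' Multiplication variants: semiring-like algebras for matrix products
#'
#' A multiplication variant bundles a value domain, a combination operator
#' \code{otimes}, an aggregation operator \code{oplus}, and an absorbing zero
#' element \code{phi} with \code{a oplus phi = a} and \code{a otimes phi = phi}.
#' Only associativity of \code{oplus} and the existence of \code{phi} are
#' required; distributivity is deliberately not assumed.  The four standard
#' variants (dot product, min-plus, max-plus, boolean) cover the shipped
#' problem instantiations.
#'
#' @param name identifier used for kernel lookup.
#' @param domain `"real"` or `"boolean"`.
#' @param otimes scalar combination operator (a function of two values).
#' @param oplus scalar aggregation operator (a function of two values).
#' @param phi the zero element (absorbing for `otimes`, neutral for `oplus`).
#' @param oplus_commutative logical; must be `TRUE` for the multiple-string
#'   engine, where split points carry no natural left-to-right order.
#' @param fold_product vectorized evaluator of
#'   `oplus` over `otimes(x[t], y[t])` in increasing `t`; supplied
#'   automatically for the standard variants, derived from the scalar
#'   operators otherwise.
#' @param oplus_all vectorized `oplus`-fold of its arguments in order;
#'   derived from the scalar operator when not supplied.
#' @return an object of class `mult_variant`.
#' @seealso [standard_variants()], [mat_mult()], [mat_add()]
#' @export
mult_variant <- function(name, domain, otimes, oplus, phi,
                         oplus_commutative = TRUE,
                         fold_product = NULL, oplus_all = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            domain %in% c("real", "boolean"),
            is.function(otimes), is.function(oplus))
  if (is.null(oplus_all)) {
    oplus_all <- function(...) {
      vals <- c(...)
      if (length(vals) == 0L) return(phi)
      Reduce(oplus, vals)
    }
  }
  if (is.null(fold_product)) {
    fold_product <- function(x, y) {
      if (length(x) == 0L) return(phi)
      acc <- otimes(x[[1L]], y[[1L]])
      for (t in seq_along(x)[-1L]) acc <- oplus(acc, otimes(x[[t]], y[[t]]))
      acc
    }
  }
  structure(list(name = name, domain = domain,
                 otimes = otimes, oplus = oplus, phi = phi,
                 oplus_commutative = isTRUE(oplus_commutative),
                 oplus_associative = TRUE,
                 fold_product = fold_product, oplus_all = oplus_all),
            class = "mult_variant")
}

#' @export
print.mult_variant <- function(x, ...) {
  cat(sprintf("<mult_variant %s: domain=%s, phi=%s, commutative oplus=%s>\n",
              x$name, x$domain, format(x$phi), x$oplus_commutative))
  invisible(x)
}

#' The standard multiplication variants
#'
#' Returns the four standard algebras:
#' \describe{
#'   \item{dot}{numeric; `otimes` = `*`, `oplus` = `+`, `phi` = 0.}
#'   \item{min_plus}{numeric (tropical); `otimes` = `+`, `oplus` = `min`,
#'     `phi` = `+Inf`.}
#'   \item{max_plus}{numeric (tropical); `otimes` = `+`, `oplus` = `max`,
#'     `phi` = `-Inf`.}
#'   \item{boolean}{logical; `otimes` = AND, `oplus` = OR, `phi` = `FALSE`.}
#' }
#' Infinities are represented by actual floating infinities (so `-Inf + x`
#' is `-Inf` natively), which keeps the kernels vectorizable.
#'
#' @return named list of [mult_variant] objects.
#' @examples
#' v <- standard_variants()$max_plus
#' v$otimes(3, v$phi)  # -Inf: phi absorbs under otimes
#' @export
standard_variants <- function() {
  dot <- mult_variant(
    "dot", "real", `*`, `+`, 0,
    fold_product = function(x, y) if (length(x)) sum(x * y) else 0,
    oplus_all = function(...) sum(...))
  min_plus <- mult_variant(
    "min_plus", "real", `+`, function(a, b) min(a, b), Inf,
    fold_product = function(x, y) if (length(x)) min(x + y) else Inf,
    oplus_all = function(...) min(...))
  max_plus <- mult_variant(
    "max_plus", "real", `+`, function(a, b) max(a, b), -Inf,
    fold_product = function(x, y) if (length(x)) max(x + y) else -Inf,
    oplus_all = function(...) max(...))
  boolean <- mult_variant(
    "boolean", "boolean", `&`, `|`, FALSE,
    fold_product = function(x, y) if (length(x)) any(x & y) else FALSE,
    oplus_all = function(...) any(...))
  list(dot = dot, min_plus = min_plus, max_plus = max_plus, boolean = boolean)
}

#' Allocate an all-phi matrix for a variant
#'
#' @param v a [mult_variant].
#' @param nrow,ncol dimensions.
#' @return matrix filled with `v$phi` (logical for the boolean domain).
#' @export
phi_matrix <- function(v, nrow, ncol = nrow) {
  matrix(v$phi, nrow = nrow, ncol = ncol)
}

#' Entrywise matrix addition under a variant
#'
#' Computes `Z[i,j] = X[i,j] oplus Y[i,j]`, left argument first (the order
#' would matter if a non-commutative `oplus` were ever registered).
#'
#' @param X,Y matrices of equal shape over the variant's domain.
#' @param v a [mult_variant].
#' @return matrix of the same shape.
#' @export
mat_add <- function(X, Y, v) {
  if (!all(dim(X) == dim(Y))) {
    stop("mat_add: shape mismatch (", paste(dim(X), collapse = "x"),
         " vs ", paste(dim(Y), collapse = "x"), ")", call. = FALSE)
  }
  switch(v$name,
         dot = X + Y,
         max_plus = pmax(X, Y),
         min_plus = pmin(X, Y),
         boolean = X | Y,
         { # generic fallback: elementwise scalar oplus, left-first
           Z <- X
           for (idx in seq_along(X)) Z[idx] <- v$oplus(X[[idx]], Y[[idx]])
           Z
         })
}

#' Matrix multiplication under a variant
#'
#' Computes `Z[i,j]` as the `oplus`-fold, in increasing inner index `q`, of
#' `X[i,q] otimes Y[q,j]`.  When the inner dimension is zero the result is
#' the all-`phi` matrix.  The actual arithmetic is delegated to a registered
#' kernel (see [register_kernel()]); kernels that reorder the accumulation
#' are admitted only for variants with a commutative `oplus`.
#'
#' @param X `n1 x n2` matrix, `Y` `n2 x n3` matrix over the variant's domain.
#' @param v a [mult_variant].
#' @param kernel kernel name; `"default"` picks the vectorized kernel
#'   registered for the variant.
#' @return `n1 x n3` matrix.
#' @export
mat_mult <- function(X, Y, v, kernel = "default") {
  if (ncol(X) != nrow(Y)) {
    stop("mat_mult: inner dimension mismatch (", ncol(X), " vs ", nrow(Y), ")",
         call. = FALSE)
  }
  fn <- get_kernel(v, kernel)
  fn(X, Y)
}

#' Check the three block-concatenation identities of semiring products
#'
#' Verifies, for given conformable blocks, that (1) stacking rows commutes
#' with multiplication, (2) splitting columns commutes with multiplication,
#' and (3) `(X1 ox Y1) op (X2 ox Y2) = [X1 X2] ox rbind(Y1, Y2)`.  These
#' identities follow from associativity of `oplus` alone and are what the
#' divide-and-conquer engines rely on when they defer split contributions to
#' block products.
#'
#' @param X1,X2,Y,Y1,Y2 conformable matrices: `X1`, `X2` with
#'   `ncol == nrow(Y)`; `Y1`, `Y2` with `nrow == ncol(X1)`;
#'   identity (3) additionally pairs `X1` with `Y1` and `X2` with `Y2`.
#' @param v a [mult_variant].
#' @param tol relative tolerance for real domains (boolean is exact).
#' @param kernel kernel used for the products.
#' @return `TRUE` iff all three identities hold within tolerance.
#' @export
check_block_identities <- function(X1, X2, Y, Y1, Y2, v, tol = 1e-9,
                                   kernel = "default") {
  eq1_lhs <- mat_mult(rbind(X1, X2), Y, v, kernel)
  eq1_rhs <- rbind(mat_mult(X1, Y, v, kernel), mat_mult(X2, Y, v, kernel))
  eq2_lhs <- mat_mult(X1, cbind(Y1, Y2), v, kernel)
  eq2_rhs <- cbind(mat_mult(X1, Y1, v, kernel), mat_mult(X1, Y2, v, kernel))
  eq3_lhs <- mat_add(mat_mult(X1, Y1, v, kernel), mat_mult(X2, Y2, v, kernel), v)
  eq3_rhs <- mat_mult(cbind(X1, X2), rbind(Y1, Y2), v, kernel)
  matrices_close(eq1_lhs, eq1_rhs, v, tol) &&
    matrices_close(eq2_lhs, eq2_rhs, v, tol) &&
    matrices_close(eq3_lhs, eq3_rhs, v, tol)
}

#' Compare two matrices up to a domain-appropriate tolerance
#'
#' Boolean matrices are compared exactly; real matrices entrywise with
#' relative tolerance `tol` (absolute below magnitude 1), treating equal
#' infinities as equal.
#'
#' @param A,B matrices of equal shape.
#' @param v a [mult_variant] (decides exact vs tolerant comparison).
#' @param tol relative tolerance for real domains.
#' @return logical scalar.
#' @export
matrices_close <- function(A, B, v, tol = 1e-9) {
  if (!all(dim(A) == dim(B))) return(FALSE)
  if (v$domain == "boolean") return(identical(as.vector(A), as.vector(B)))
  a <- as.vector(A); b <- as.vector(B)
  same_inf <- is.infinite(a) & is.infinite(b) & (sign(a) == sign(b))
  d <- abs(a - b) <= tol * pmax(1, abs(a), abs(b))
  all(d | same_inf)
}
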
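#' Inside problem specification
#'
#' Describes a family of mutually recursive inside properties
#' \eqn{\beta^1, \ldots, \beta^K} over one shared index space of positions
#' `0..N-1`.  Property `k` may depend on split-combination values
#' \eqn{\mu^k_{i,j} = \oplus_{q \in (i,j)} \beta^{k'}_{i,q} \otimes
#' \beta^{k''}_{q,j}} for one or more pairs `(k', k'')` (each pair is a
#' "slot" accumulated independently, which lets CKY-style problems with
#' many binary rules per nonterminal share one property set per symbol),
#' plus a per-cell `finalize` callback that combines the slot values with
#' previously finalized properties.
#'
#' `finalize(i, j, mu, read)` receives 0-based positions, `mu` as a list of
#' length `K` (element `k` a vector with one value per slot of property `k`,
#' `phi`-valued when a slot's split range is empty) and `read(k, i2, j2)`,
#' an accessor returning finalized values (`phi` for out-of-range indices).
#' It must return `K` values in property order.  It may only read strict
#' sub-ranges of `[i, j]`, or the same cell for properties finalized earlier
#' in the order — the engines finalize cells so that exactly those values
#' are available.
#'
#' @param K number of properties.
#' @param variant the [mult_variant] shared by all slots.
#' @param mu_specs list of length `K`; element `k` is a list of integer
#'   pairs `c(k1, k2)` (possibly empty) defining the slots of property `k`.
#' @param finalize per-cell callback, see Details.
#' @param property_names optional names, defaults to `beta1..betaK`.
#' @param cell_valid optional predicate `function(i, j)`; cells with
#'   `i > j` are always invalid, this predicate may mask further cells
#'   (used by the multiple-string reduction).  Invalid cells keep `phi`.
#' @return object of class `inside_spec`.
#' @seealso [run_inside()], [run_inside_classical()]
#' @export
inside_spec <- function(K, variant, mu_specs, finalize,
                        property_names = paste0("beta", seq_len(K)),
                        cell_valid = NULL) {
  stopifnot(K >= 1L, inherits(variant, "mult_variant"),
            is.list(mu_specs), length(mu_specs) == K,
            is.function(finalize), length(property_names) == K)
  for (k in seq_len(K)) {
    for (pair in mu_specs[[k]]) {
      if (length(pair) != 2L || any(pair < 1L) || any(pair > K)) {
        stop("mu_specs[[", k, "]] must contain pairs of property indices in 1..K",
             call. = FALSE)
      }
    }
  }
  structure(list(K = as.integer(K), variant = variant, mu_specs = mu_specs,
                 finalize = finalize, property_names = property_names,
                 cell_valid = cell_valid),
            class = "inside_spec")
}

.cell_ok <- function(spec, i, j) {
  i <= j && (is.null(spec$cell_valid) || spec$cell_valid(i, j))
}

.new_inside_ws <- function(N, spec, kernel, cutoff, verify) {
  v <- spec$variant
  ws <- new.env(parent = emptyenv())
  ws$N <- N
  ws$spec <- spec
  ws$v <- v
  ws$kern <- get_kernel(v, kernel)
  ws$cutoff <- as.integer(cutoff)
  ws$verify <- isTRUE(verify) && N <= 128L
  ws$B <- lapply(seq_len(spec$K), function(k) phi_matrix(v, N))
  ws$Mu <- lapply(seq_len(spec$K), function(k)
    lapply(spec$mu_specs[[k]], function(p) phi_matrix(v, N)))
  phi <- v$phi
  ws$read <- function(k, ii, jj) {
    if (ii < 0L || jj < 0L || ii >= N || jj >= N) return(phi)
    ws$B[[k]][ii + 1L, jj + 1L]
  }
  if (ws$verify) {
    ws$oracle <- run_inside_classical(N, spec)
    ws$read <- function(k, ii, jj) {
      if (ii < 0L || jj < 0L || ii >= N || jj >= N) return(phi)
      if (ii < ws$cur_i || jj > ws$cur_j) {
        stop("finalize read outside the current cell's dependency region: ",
             "beta", k, "[", ii, ",", jj, "] from cell [", ws$cur_i, ",",
             ws$cur_j, "]", call. = FALSE)
      }
      ws$B[[k]][ii + 1L, jj + 1L]
    }
  }
  ws
}

# Fold the remaining in-block split contributions for cell (i, j) of base
# block (I, J) and combine them, in increasing-q order, with the slot's
# accumulated between-block value.
.inside_cell_mu <- function(ws, I, J, i, j) {
  spec <- ws$spec; v <- ws$v
  mu <- vector("list", spec$K)
  disjoint <- I[2L] < J[1L]
  for (k in seq_len(spec$K)) {
    slots <- spec$mu_specs[[k]]
    nt <- length(slots)
    if (nt == 0L) { mu[[k]] <- v$phi[0]; next }
    vals <- vector(mode = typeof(v$phi), length = nt)
    for (t in seq_len(nt)) {
      k1 <- slots[[t]][1L]; k2 <- slots[[t]][2L]
      acc <- ws$Mu[[k]][[t]][i + 1L, j + 1L]
      if (disjoint) {
        left <- if (i < I[2L]) (i + 1L):I[2L] else integer(0)
        right <- if (J[1L] < j) J[1L]:(j - 1L) else integer(0)
        lv <- if (length(left))
          v$fold_product(ws$B[[k1]][i + 1L, left + 1L],
                         ws$B[[k2]][left + 1L, j + 1L]) else v$phi
        rv <- if (length(right))
          v$fold_product(ws$B[[k1]][i + 1L, right + 1L],
                         ws$B[[k2]][right + 1L, j + 1L]) else v$phi
        vals[t] <- v$oplus_all(lv, acc, rv)
      } else {
        qs <- if (j - i >= 2L) (i + 1L):(j - 1L) else integer(0)
        fv <- if (length(qs))
          v$fold_product(ws$B[[k1]][i + 1L, qs + 1L],
                         ws$B[[k2]][qs + 1L, j + 1L]) else v$phi
        vals[t] <- v$oplus_all(fv, acc)
      }
    }
    mu[[k]] <- vals
  }
  mu
}

.inside_finalize_cell <- function(ws, i, j, mu) {
  spec <- ws$spec
  if (ws$verify) { ws$cur_i <- i; ws$cur_j <- j }
  vals <- spec$finalize(i, j, mu, ws$read)
  if (length(vals) != spec$K) {
    stop("finalize returned ", length(vals), " values, expected K = ",
         spec$K, call. = FALSE)
  }
  for (k in seq_len(spec$K)) ws$B[[k]][i + 1L, j + 1L] <- vals[[k]]
  invisible(NULL)
}

# classical completion of one base block (columns ascending, rows
# descending, so every in-block dependency is finalized before use)
.inside_block <- function(ws, I, J) {
  spec <- ws$spec
  for (j in J[1L]:J[2L]) {
    for (i in I[2L]:I[1L]) {
      if (j < i || !.cell_ok(spec, i, j)) next
      mu <- .inside_cell_mu(ws, I, J, i, j)
      .inside_finalize_cell(ws, i, j, mu)
    }
  }
}

.inside_update_vertical <- function(ws, I, L, J2) {
  ri <- (I[1L]:I[2L]) + 1L
  li <- (L[1L]:L[2L]) + 1L
  ci <- (J2[1L]:J2[2L]) + 1L
  v <- ws$v
  for (k in seq_len(ws$spec$K)) {
    slots <- ws$spec$mu_specs[[k]]
    for (t in seq_along(slots)) {
      k1 <- slots[[t]][1L]; k2 <- slots[[t]][2L]
      P <- ws$kern(ws$B[[k1]][ri, li, drop = FALSE],
                   ws$B[[k2]][li, ci, drop = FALSE])
      # accumulated value first: the new split points lie to the right
      ws$Mu[[k]][[t]][ri, ci] <-
        mat_add(ws$Mu[[k]][[t]][ri, ci, drop = FALSE], P, v)
    }
  }
}

.inside_update_horizontal <- function(ws, I2, L, J) {
  ri <- (I2[1L]:I2[2L]) + 1L
  li <- (L[1L]:L[2L]) + 1L
  ci <- (J[1L]:J[2L]) + 1L
  v <- ws$v
  for (k in seq_len(ws$spec$K)) {
    slots <- ws$spec$mu_specs[[k]]
    for (t in seq_along(slots)) {
      k1 <- slots[[t]][1L]; k2 <- slots[[t]][2L]
      P <- ws$kern(ws$B[[k1]][ri, li, drop = FALSE],
                   ws$B[[k2]][li, ci, drop = FALSE])
      # new split points are smaller than the accumulated ones: new first
      ws$Mu[[k]][[t]][ri, ci] <-
        mat_add(P, ws$Mu[[k]][[t]][ri, ci, drop = FALSE], v)
    }
  }
}

.check_inside_pre <- function(ws, I, J) {
  spec <- ws$spec; v <- ws$v; N <- ws$N
  sq <- I[1L]:J[2L]
  for (k in seq_len(spec$K)) {
    for (jj in sq) for (ii in sq) {
      in_block <- ii >= I[1L] && ii <= I[2L] && jj >= J[1L] && jj <= J[2L]
      if (in_block) next
      got <- ws$B[[k]][ii + 1L, jj + 1L]
      want <- ws$oracle[[k]][ii + 1L, jj + 1L]
      if (!matrices_close(matrix(got), matrix(want), v, 1e-9)) {
        stop("inside pre-condition violated: beta", k, "[", ii, ",", jj,
             "] not finalized on entry to block ([", I[1L], ",", I[2L],
             "],[", J[1L], ",", J[2L], "])", call. = FALSE)
      }
    }
    slots <- spec$mu_specs[[k]]
    mid <- if (I[2L] + 1L <= J[1L] - 1L) (I[2L] + 1L):(J[1L] - 1L) else integer(0)
    for (t in seq_along(slots)) {
      k1 <- slots[[t]][1L]; k2 <- slots[[t]][2L]
      ri <- (I[1L]:I[2L]) + 1L; ci <- (J[1L]:J[2L]) + 1L
      want <- if (length(mid))
        mat_mult(ws$oracle[[k1]][ri, mid + 1L, drop = FALSE],
                 ws$oracle[[k2]][mid + 1L, ci, drop = FALSE], v, "naive")
      else phi_matrix(v, length(ri), length(ci))
      got <- ws$Mu[[k]][[t]][ri, ci, drop = FALSE]
      if (!matrices_close(got, want, v, 1e-9)) {
        stop("inside pre-condition violated: mu accumulation for property ",
             k, " slot ", t, " wrong on entry to block ([", I[1L], ",",
             I[2L], "],[", J[1L], ",", J[2L], "])", call. = FALSE)
      }
    }
  }
  invisible(NULL)
}

.inside_rec <- function(ws, I, J) {
  if (J[2L] < I[1L]) return(invisible(NULL))  # strictly lower triangle
  if (ws$verify) .check_inside_pre(ws, I, J)
  lenI <- I[2L] - I[1L] + 1L
  lenJ <- J[2L] - J[1L] + 1L
  if (max(lenI, lenJ) <= ws$cutoff) {
    .inside_block(ws, I, J)
    return(invisible(NULL))
  }
  if (lenI <= lenJ) {
    half <- lenJ %/% 2L
    J1 <- c(J[1L], J[1L] + half - 1L)
    J2 <- c(J[1L] + half, J[2L])
    .inside_rec(ws, I, J1)
    if (I[2L] < J[1L]) .inside_update_vertical(ws, I, J1, J2)
    .inside_rec(ws, I, J2)
  } else {
    half <- lenI %/% 2L
    I2 <- c(I[1L], I[1L] + half - 1L)
    I1 <- c(I[1L] + half, I[2L])
    .inside_rec(ws, I1, J)
    if (I[2L] < J[1L]) .inside_update_horizontal(ws, I2, I1, J)
    .inside_rec(ws, I2, J)
  }
  invisible(NULL)
}

#' Run the divide-and-conquer inside engine
#'
#' Fills the `K` property matrices of an [inside_spec] over the index space
#' `0..N-1` by recursive halving: each off-diagonal block receives its
#' split-combination contributions through block matrix products (delegated
#' to the selected kernel) before its cells are finalized, so the per-cell
#' work is constant and the cubic split scan of the classical dynamic
#' program is replaced by matrix multiplication.  Blocks no larger than
#' `cutoff` are completed by the classical per-cell loop.
#'
#' @param N index-space size (for a string of length `n`, `N = n + 1`
#'   positions).
#' @param spec an [inside_spec].
#' @param kernel kernel name for the block products.
#' @param cutoff recursion cutoff; results are invariant to it.
#' @param verify if `TRUE` (and `N <= 128`), the recursion pre-condition is
#'   asserted against a freshly computed classical oracle on entry to every
#'   recursive call, and finalize reads are range-checked.
#' @return named list of `K` `N x N` matrices; entries at invalid cells
#'   (including the strict lower triangle) hold `phi`.
#' @examples
#' sp <- bp_max_spec("GCAU")
#' run_inside(5, sp)$beta1[1, 5]  # best pairing count of "GCAU"
#' @export
run_inside <- function(N, spec, kernel = "default", cutoff = 32L,
                       verify = FALSE) {
  stopifnot(N >= 1L, inherits(spec, "inside_spec"), cutoff >= 1L)
  ws <- .new_inside_ws(N, spec, kernel, cutoff, verify)
  .inside_rec(ws, c(0L, N - 1L), c(0L, N - 1L))
  out <- ws$B
  names(out) <- spec$property_names
  out
}

#' Classical bottom-up inside dynamic program
#'
#' Reference evaluator for an [inside_spec]: fills cells column by column
#' (rows descending within a column), computing every split-combination
#' value by a direct fold over the split points.  Cubic in `N`; used as the
#' correctness oracle for [run_inside()] and as an independent evaluation
#' order.
#'
#' @inheritParams run_inside
#' @return named list of `K` `N x N` matrices, identical to [run_inside()].
#' @export
run_inside_classical <- function(N, spec) {
  stopifnot(N >= 1L, inherits(spec, "inside_spec"))
  v <- spec$variant
  phi <- v$phi
  K <- spec$K
  B <- lapply(seq_len(K), function(k) phi_matrix(v, N))
  read <- function(k, ii, jj) {
    if (ii < 0L || jj < 0L || ii >= N || jj >= N) return(phi)
    B[[k]][ii + 1L, jj + 1L]
  }
  for (j in 0:(N - 1L)) {
    for (i in j:0) {
      if (!.cell_ok(spec, i, j)) next
      qs <- if (j - i >= 2L) (i + 1L):(j - 1L) else integer(0)
      mu <- vector("list", K)
      for (k in seq_len(K)) {
        slots <- spec$mu_specs[[k]]
        nt <- length(slots)
        vals <- vector(mode = typeof(phi), length = nt)
        for (t in seq_len(nt)) {
          k1 <- slots[[t]][1L]; k2 <- slots[[t]][2L]
          vals[t] <- if (length(qs))
            v$fold_product(B[[k1]][i + 1L, qs + 1L], B[[k2]][qs + 1L, j + 1L])
          else phi
        }
        mu[[k]] <- vals
      }
      vals <- spec$finalize(i, j, mu, read)
      if (length(vals) != K) {
        stop("finalize returned ", length(vals), " values, expected K = ", K,
             call. = FALSE)
      }
      for (k in seq_len(K)) B[[k]][i + 1L, j + 1L] <- vals[[k]]
    }
  }
  names(B) <- spec$property_names
  B
}
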
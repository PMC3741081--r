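#' Outside problem specification
#'
#' Describes outside properties \eqn{\alpha^1, \ldots, \alpha^K} of the
#' residual instance obtained by excising the substring between positions
#' `i` and `j` (the prefix up to `i` plus the suffix from `j`).  Property
#' `k` may carry at most one split-combination form:
#' \describe{
#'   \item{prefix}{\eqn{\mu^k_{i,j} = \oplus_{q \in [0,i)}
#'     \beta^{k_\beta}_{q,i} \otimes \alpha^{k_\alpha}_{q,j}}}
#'   \item{suffix}{\eqn{\mu^k_{i,j} = \oplus_{q \in (j,n]}
#'     \alpha^{k_\alpha}_{i,q} \otimes \beta^{k_\beta}_{j,q}}}
#'   \item{none}{no split value; `finalize` uses neighbor reads only.}
#' }
#' `finalize(i, j, mu, read_alpha, read_beta)` receives the per-property
#' `mu` vector (`phi` where a property has no form or the range is empty)
#' and accessors returning `phi` for out-of-range indices, and must return
#' `K` values.  It may read `alpha` only at strict super-ranges of
#' `[i, j]`, or at the same cell for properties earlier in the order, and
#' any finalized inside value.
#'
#' @param K number of outside properties.
#' @param variant the shared [mult_variant].
#' @param mu_specs list of length `K`: `NULL` for no form, else
#'   `list(form = "prefix"|"suffix", k_beta = , k_alpha = )`.
#' @param finalize per-cell callback, see Details.
#' @param property_names optional names, defaults to `alpha1..alphaK`.
#' @return object of class `outside_spec`.
#' @seealso [run_outside()], [run_outside_classical()]
#' @export
outside_spec <- function(K, variant, mu_specs, finalize,
                         property_names = paste0("alpha", seq_len(K))) {
  stopifnot(K >= 1L, inherits(variant, "mult_variant"),
            is.list(mu_specs), length(mu_specs) == K,
            is.function(finalize), length(property_names) == K)
  for (k in seq_len(K)) {
    ms <- mu_specs[[k]]
    if (is.null(ms)) next
    if (!is.list(ms) || !ms$form %in% c("prefix", "suffix") ||
        ms$k_beta < 1L || ms$k_alpha < 1L || ms$k_alpha > K) {
      stop("mu_specs[[", k, "]] must be NULL or list(form, k_beta, k_alpha)",
           call. = FALSE)
    }
  }
  structure(list(K = as.integer(K), variant = variant, mu_specs = mu_specs,
                 finalize = finalize, property_names = property_names),
            class = "outside_spec")
}

.new_outside_ws <- function(inside, spec, kernel, cutoff, verify) {
  v <- spec$variant
  N <- nrow(inside[[1L]])
  ws <- new.env(parent = emptyenv())
  ws$N <- N
  ws$spec <- spec
  ws$v <- v
  ws$kern <- get_kernel(v, kernel)
  ws$cutoff <- as.integer(cutoff)
  ws$verify <- isTRUE(verify) && N <= 128L
  ws$Bin <- inside
  ws$A <- lapply(seq_len(spec$K), function(k) phi_matrix(v, N))
  ws$Mu <- lapply(seq_len(spec$K), function(k)
    if (is.null(spec$mu_specs[[k]])) NULL else phi_matrix(v, N))
  phi <- v$phi
  ws$read_alpha <- function(k, ii, jj) {
    if (ii < 0L || jj < 0L || ii >= N || jj >= N) return(phi)
    ws$A[[k]][ii + 1L, jj + 1L]
  }
  ws$read_beta <- function(k, ii, jj) {
    if (ii < 0L || jj < 0L || ii >= N || jj >= N) return(phi)
    ws$Bin[[k]][ii + 1L, jj + 1L]
  }
  if (ws$verify) {
    ws$oracle <- run_outside_classical(inside, spec)
    ws$read_alpha <- function(k, ii, jj) {
      if (ii < 0L || jj < 0L || ii >= N || jj >= N) return(phi)
      if (ii > ws$cur_i || jj < ws$cur_j) {
        stop("finalize read outside the super-range dependency region: alpha",
             k, "[", ii, ",", jj, "] from cell [", ws$cur_i, ",", ws$cur_j,
             "]", call. = FALSE)
      }
      ws$A[[k]][ii + 1L, jj + 1L]
    }
  }
  ws
}

# per-cell mu: accumulated between-block value extended with the in-block
# split points, preserving increasing-q order
.outside_cell_mu <- function(ws, I, J, i, j) {
  spec <- ws$spec; v <- ws$v; N <- ws$N
  mu <- vector(mode = typeof(v$phi), length = spec$K)
  mu[] <- v$phi
  for (k in seq_len(spec$K)) {
    ms <- spec$mu_specs[[k]]
    if (is.null(ms)) next
    acc <- ws$Mu[[k]][i + 1L, j + 1L]
    if (ms$form == "prefix") {
      # covered: q in [0, min I); remaining: q in [min I, i)
      qs <- if (I[1L] < i) I[1L]:(i - 1L) else integer(0)
      fv <- if (length(qs))
        v$fold_product(ws$Bin[[ms$k_beta]][qs + 1L, i + 1L],
                       ws$A[[ms$k_alpha]][qs + 1L, j + 1L]) else v$phi
      mu[k] <- v$oplus_all(acc, fv)
    } else {
      # covered: q in (max J, n]; remaining: q in (j, max J]
      qs <- if (j < J[2L]) (j + 1L):J[2L] else integer(0)
      fv <- if (length(qs))
        v$fold_product(ws$A[[ms$k_alpha]][i + 1L, qs + 1L],
                       ws$Bin[[ms$k_beta]][j + 1L, qs + 1L]) else v$phi
      mu[k] <- v$oplus_all(fv, acc)
    }
  }
  mu
}

# classical completion of one base block: columns descending, rows
# ascending, so each cell follows all of its strict super-ranges
.outside_block <- function(ws, I, J) {
  spec <- ws$spec
  for (j in J[2L]:J[1L]) {
    for (i in I[1L]:I[2L]) {
      if (j < i) next
      mu <- .outside_cell_mu(ws, I, J, i, j)
      if (ws$verify) { ws$cur_i <- i; ws$cur_j <- j }
      vals <- spec$finalize(i, j, mu, ws$read_alpha, ws$read_beta)
      if (length(vals) != spec$K) {
        stop("finalize returned ", length(vals), " values, expected K = ",
             spec$K, call. = FALSE)
      }
      for (k in seq_len(spec$K)) ws$A[[k]][i + 1L, j + 1L] <- vals[[k]]
    }
  }
}

.check_outside_pre <- function(ws, I, J) {
  spec <- ws$spec; v <- ws$v; N <- ws$N
  for (k in seq_len(spec$K)) {
    for (ii in 0:I[2L]) for (jj in J[1L]:(N - 1L)) {
      in_block <- ii >= I[1L] && ii <= I[2L] && jj >= J[1L] && jj <= J[2L]
      if (in_block) next
      got <- ws$A[[k]][ii + 1L, jj + 1L]
      want <- ws$oracle[[k]][ii + 1L, jj + 1L]
      if (!matrices_close(matrix(got), matrix(want), v, 1e-9)) {
        stop("outside pre-condition violated: alpha", k, "[", ii, ",", jj,
             "] not finalized on entry to block ([", I[1L], ",", I[2L],
             "],[", J[1L], ",", J[2L], "])", call. = FALSE)
      }
    }
    ms <- spec$mu_specs[[k]]
    if (is.null(ms)) next
    ri <- (I[1L]:I[2L]) + 1L; ci <- (J[1L]:J[2L]) + 1L
    if (ms$form == "prefix") {
      qs <- if (I[1L] >= 1L) 0:(I[1L] - 1L) else integer(0)
      want <- if (length(qs))
        mat_mult(t(ws$Bin[[ms$k_beta]][qs + 1L, ri, drop = FALSE]),
                 ws$oracle[[ms$k_alpha]][qs + 1L, ci, drop = FALSE], v, "naive")
      else phi_matrix(v, length(ri), length(ci))
    } else {
      qs <- if (J[2L] + 1L <= N - 1L) (J[2L] + 1L):(N - 1L) else integer(0)
      want <- if (length(qs))
        mat_mult(ws$oracle[[ms$k_alpha]][ri, qs + 1L, drop = FALSE],
                 t(ws$Bin[[ms$k_beta]][ci, qs + 1L, drop = FALSE]), v, "naive")
      else phi_matrix(v, length(ri), length(ci))
    }
    got <- ws$Mu[[k]][ri, ci, drop = FALSE]
    if (!matrices_close(got, want, v, 1e-9)) {
      stop("outside pre-condition violated: mu accumulation for property ", k,
           " wrong on entry to block ([", I[1L], ",", I[2L], "],[", J[1L],
           ",", J[2L], "])", call. = FALSE)
    }
  }
  invisible(NULL)
}

.outside_rec <- function(ws, I, J) {
  if (J[2L] < I[1L]) return(invisible(NULL))  # entirely invalid
  if (ws$verify) .check_outside_pre(ws, I, J)
  lenI <- I[2L] - I[1L] + 1L
  lenJ <- J[2L] - J[1L] + 1L
  if (max(lenI, lenJ) <= ws$cutoff) {
    .outside_block(ws, I, J)
    return(invisible(NULL))
  }
  if (lenI <= lenJ) {
    half <- lenJ %/% 2L
    J2 <- c(J[1L], J[1L] + half - 1L)   # lower column indices, done second
    J1 <- c(J[1L] + half, J[2L])        # higher column indices, done first
    .outside_rec(ws, I, J1)
    .outside_update_vertical(ws, I, J1, J2)
    .outside_rec(ws, I, J2)
  } else {
    half <- lenI %/% 2L
    I1 <- c(I[1L], I[1L] + half - 1L)   # lower row indices, done first
    I2 <- c(I[1L] + half, I[2L])
    .outside_rec(ws, I1, J)
    .outside_update_horizontal(ws, I1, I2, J)
    .outside_rec(ws, I2, J)
  }
  invisible(NULL)
}

# suffix-form bridging after the right sibling: the freshly finalized
# columns L = J1 supply the split points between (j, max J] for rows of J2
.outside_update_vertical <- function(ws, I, L, J2) {
  if (J2[2L] < I[1L]) return(invisible(NULL))
  ri <- (I[1L]:I[2L]) + 1L
  li <- (L[1L]:L[2L]) + 1L
  ci <- (J2[1L]:J2[2L]) + 1L
  v <- ws$v
  for (k in seq_len(ws$spec$K)) {
    ms <- ws$spec$mu_specs[[k]]
    if (is.null(ms) || ms$form != "suffix") next
    P <- ws$kern(ws$A[[ms$k_alpha]][ri, li, drop = FALSE],
                 t(ws$Bin[[ms$k_beta]][ci, li, drop = FALSE]))
    # new split points are the smaller q: new first, accumulated second
    ws$Mu[[k]][ri, ci] <- mat_add(P, ws$Mu[[k]][ri, ci, drop = FALSE], v)
  }
}

# prefix-form bridging after the top sibling: rows L = I1 supply the split
# points in [min I, min I2) for the rows of I2
.outside_update_horizontal <- function(ws, L, I2, J) {
  if (J[2L] < I2[1L]) return(invisible(NULL))
  ri <- (I2[1L]:I2[2L]) + 1L
  li <- (L[1L]:L[2L]) + 1L
  ci <- (J[1L]:J[2L]) + 1L
  v <- ws$v
  for (k in seq_len(ws$spec$K)) {
    ms <- ws$spec$mu_specs[[k]]
    if (is.null(ms) || ms$form != "prefix") next
    P <- ws$kern(t(ws$Bin[[ms$k_beta]][li, ri, drop = FALSE]),
                 ws$A[[ms$k_alpha]][li, ci, drop = FALSE])
    # accumulated q in [0, min I) come first, the new ones after
    ws$Mu[[k]][ri, ci] <- mat_add(ws$Mu[[k]][ri, ci, drop = FALSE], P, v)
  }
}

#' Run the divide-and-conquer outside engine
#'
#' Computes the `K` outside property matrices of an [outside_spec] from
#' finalized inside matrices, mirroring the inside recursion from the
#' upper-right corner: the higher column half / lower row half of each
#' block is completed first, and the freshly finalized strip bridges the
#' split-combination values of its sibling through one transposed block
#' product per property with a prefix or suffix form.
#'
#' @param inside named list of finalized inside matrices (all `N x N`).
#' @param spec an [outside_spec].
#' @param kernel,cutoff,verify as in [run_inside()].
#' @return named list of `K` `N x N` outside matrices; invalid cells
#'   (`j < i`) hold `phi`.
#' @export
run_outside <- function(inside, spec, kernel = "default", cutoff = 32L,
                        verify = FALSE) {
  stopifnot(inherits(spec, "outside_spec"), is.list(inside),
            length(inside) >= 1L, cutoff >= 1L)
  N <- nrow(inside[[1L]])
  if (is.null(N) || any(vapply(inside, function(m) !all(dim(m) == N), logical(1)))) {
    stop("inside matrices must all be square of equal size", call. = FALSE)
  }
  ws <- .new_outside_ws(inside, spec, kernel, cutoff, verify)
  .outside_rec(ws, c(0L, N - 1L), c(0L, N - 1L))
  out <- ws$A
  names(out) <- spec$property_names
  out
}

#' Classical outside dynamic program
#'
#' Reference evaluator: computes cells in an order where every cell
#' follows all of its strict super-ranges (rows ascending, columns
#' descending within a row), with every split-combination value evaluated
#' by a direct fold.  Cubic; the correctness oracle for [run_outside()].
#'
#' @inheritParams run_outside
#' @return named list of `K` `N x N` matrices, identical to
#'   [run_outside()].
#' @export
run_outside_classical <- function(inside, spec) {
  stopifnot(inherits(spec, "outside_spec"))
  v <- spec$variant
  phi <- v$phi
  N <- nrow(inside[[1L]])
  K <- spec$K
  A <- lapply(seq_len(K), function(k) phi_matrix(v, N))
  read_alpha <- function(k, ii, jj) {
    if (ii < 0L || jj < 0L || ii >= N || jj >= N) return(phi)
    A[[k]][ii + 1L, jj + 1L]
  }
  read_beta <- function(k, ii, jj) {
    if (ii < 0L || jj < 0L || ii >= N || jj >= N) return(phi)
    inside[[k]][ii + 1L, jj + 1L]
  }
  for (i in 0:(N - 1L)) {
    for (j in (N - 1L):i) {
      mu <- vector(mode = typeof(phi), length = K)
      mu[] <- phi
      for (k in seq_len(K)) {
        ms <- spec$mu_specs[[k]]
        if (is.null(ms)) next
        if (ms$form == "prefix") {
          qs <- if (i >= 1L) 0:(i - 1L) else integer(0)
          mu[k] <- if (length(qs))
            v$fold_product(inside[[ms$k_beta]][qs + 1L, i + 1L],
                           A[[ms$k_alpha]][qs + 1L, j + 1L]) else phi
        } else {
          qs <- if (j + 1L <= N - 1L) (j + 1L):(N - 1L) else integer(0)
          mu[k] <- if (length(qs))
            v$fold_product(A[[ms$k_alpha]][i + 1L, qs + 1L],
                           inside[[ms$k_beta]][j + 1L, qs + 1L]) else phi
        }
      }
      vals <- spec$finalize(i, j, mu, read_alpha, read_beta)
      if (length(vals) != K) {
        stop("finalize returned ", length(vals), " values, expected K = ", K,
             call. = FALSE)
      }
      for (k in seq_len(K)) A[[k]][i + 1L, j + 1L] <- vals[[k]]
    }
  }
  names(A) <- spec$property_names
  A
}
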
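# Simultaneous alignment and folding (SAF) of several RNA strings.
#
# An alignment column corresponds to a sub-instance S[Q, Q'] with Q' a
# local increment of Q: strings whose index advances contribute their
# base, the others a gap.  An alignment-with-folding scores
# sum_r rho(col_r) + sum_{a.b in F} tau(col_a, col_b); the inside property
# beta[X, Y] is the best such score for the sub-instance S[X, Y].

# column of S between Q and Q' (Q' a local increment): character vector
# with "-" for strings that do not advance
.saf_column <- function(chars, Q, Q2) {
  m <- length(Q)
  col <- character(m)
  for (p in seq_len(m)) {
    col[p] <- if (Q2[p] == Q[p] + 1L) chars[[p]][Q[p] + 1L] else "-"
  }
  col
}

#' Column scoring for simultaneous alignment and folding
#'
#' `rho(col)` scores one alignment column: the sum over string pairs of
#' `match` (equal bases), `mismatch` (unequal bases), `gap_char` (base
#' against gap) or `gap_gap` (both gaps).  `tau(colA, colB)` scores a
#' paired column pair: the sum over strings of `pair_comp` when both
#' columns carry complementary bases for that string, else `pair_bad`.
#' All six constants are configurable; `rho` and `tau` run in time linear
#' in the number of strings.
#'
#' @param match,mismatch,gap_char,gap_gap,pair_comp,pair_bad scoring
#'   constants (defaults 1, -1, -2, 0, 2, -3).
#' @param rho,tau optional custom functions overriding the constant-based
#'   defaults: `rho(col)` and `tau(colA, colB)` over character vectors
#'   with `"-"` marking gaps.
#' @return object of class `saf_scoring` with elements `rho`, `tau`.
#' @export
saf_scoring <- function(match = 1, mismatch = -1, gap_char = -2, gap_gap = 0,
                        pair_comp = 2, pair_bad = -3,
                        rho = NULL, tau = NULL) {
  if (is.null(rho)) {
    rho <- function(col) {
      m <- length(col)
      if (m == 1L) return(0)
      sc <- 0
      for (p in seq_len(m - 1L)) for (p2 in (p + 1L):m) {
        a <- col[p]; b <- col[p2]
        sc <- sc + if (a == "-" && b == "-") gap_gap
        else if (a == "-" || b == "-") gap_char
        else if (a == b) match else mismatch
      }
      sc
    }
  }
  if (is.null(tau)) {
    tau <- function(colA, colB) {
      sc <- 0
      for (p in seq_along(colA)) {
        a <- colA[p]; b <- colB[p]
        sc <- sc + if (a != "-" && b != "-" && .comp_chr(a, b)) pair_comp
        else pair_bad
      }
      sc
    }
  }
  structure(list(rho = rho, tau = tau), class = "saf_scoring")
}

#' @rdname saf_scoring
#' @details `saf_scoring_fold()` is the single-string reduction scoring:
#'   `rho = 0` and `tau = +1` for a complementary base pair, `-Inf`
#'   otherwise.  With one input string the alignment degenerates to the
#'   string itself and the optimal score equals the maximum base-pair
#'   count, which makes the reduction testable against
#'   [fold_max_pairs()].
#' @export
saf_scoring_fold <- function() {
  saf_scoring(
    rho = function(col) 0,
    tau = function(colA, colB) {
      if (all(colA != "-") && all(colB != "-") &&
          all(.comp_chr(colA, colB))) 1 else -Inf
    })
}

#' Simultaneous alignment and folding via the multiple-string engine
#'
#' Builds the max-plus inside spec for the alignment-with-folding
#' recurrence: the split term is the lattice vector multiplication
#' \eqn{\mu_{X,Y} = \max_{Q \in (X,Y)} (\beta_{X,Q} + \beta_{Q,Y})}
#' handled by the engine's block products, and the closing term maximizes
#' over pairs of first/last alignment columns (local increments of `X`
#' times local decrements of `Y`, at most `2^(2m)` combinations) inside
#' the per-cell finalize.  Base case `beta[X, X] = 0`.
#'
#' @param S a [multistring_instance].
#' @param scoring a [saf_scoring].
#' @return `saf_spec` returns an [inside_spec] over the linearized
#'   lattice; `saf_score` the optimal score `beta[0bar, N]`.
#' @examples
#' saf_score(multistring_instance(c("ACGU", "AGU")), saf_scoring())
#' @export
saf_spec <- function(S, scoring) {
  stopifnot(inherits(S, "multistring_instance"),
            inherits(scoring, "saf_scoring"))
  codec <- position_codec(S$lengths)
  chars <- lapply(S$strings, function(s) strsplit(s, "")[[1]])
  v <- standard_variants()$max_plus
  finalize <- function(i, j, mu, read) {
    if (i == j) return(0)
    X <- codec_decode(i, codec)
    Y <- codec_decode(j, codec)
    best <- mu[[1L]][1L]
    # single-column alignment: Y is a local increment of X, no pair formed
    # (covered by neither the closing-pair term nor a lattice split)
    if (all(Y - X <= 1L)) {
      cand <- scoring$rho(.saf_column(chars, X, Y))
      if (cand > best) best <- cand
    }
    for (Xp in local_increments(X, codec)) {
      if (!position_leq(Xp, Y)) next
      colA <- .saf_column(chars, X, Xp)
      rA <- scoring$rho(colA)
      for (Yp in local_decrements(Y, codec)) {
        if (!position_leq(X, Yp) || !position_leq(Xp, Yp)) next
        inner <- read(1L, codec_encode(Xp, codec), codec_encode(Yp, codec))
        if (inner == -Inf) next
        colB <- .saf_column(chars, Yp, Y)
        cand <- inner + rA + scoring$rho(colB) + scoring$tau(colA, colB)
        if (cand > best) best <- cand
      }
    }
    best
  }
  inside_spec(1L, v, list(list(c(1L, 1L))), finalize,
              property_names = "beta")
}

#' @rdname saf_spec
#' @param kernel,cutoff,max_size passed to [run_multistring_inside()].
#' @export
saf_score <- function(S, scoring = saf_scoring(), kernel = "default",
                      cutoff = 32L, max_size = 4096L) {
  if (!inherits(S, "multistring_instance")) S <- multistring_instance(S)
  B <- run_multistring_inside(S, saf_spec(S, scoring), kernel = kernel,
                              cutoff = cutoff, max_size = max_size)
  N <- as.integer(position_codec(S$lengths)$size)
  B$beta[1L, N]
}
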
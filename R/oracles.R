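# Brute-force and enumeration oracles.  These deliberately share no code
# with the divide-and-conquer engines (nor with the classical-order
# evaluators): they enumerate solution spaces directly or run plain
# loops/memoized recursions, and serve as the acceptance surface.
# Guards are hard errors — an oracle that silently truncates would
# invalidate every test built on it.

#' Enumerate all nested foldings of an RNA string
#'
#' Generates every nested set of complementary base pairs exactly once by
#' case analysis on the last base (unpaired, or paired with each
#' complementary partner).  The number of foldings grows exponentially, so
#' the string length is guarded.
#'
#' @param s RNA string with at most `max_n` bases.
#' @param max_n length guard (hard error above it).
#' @return list of [folding] objects (always contains the empty folding).
#' @export
enumerate_foldings <- function(s, max_n = 14L) {
  s <- normalize_rna(s)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n > max_n) {
    stop("enumerate_foldings: length ", n, " exceeds guard ", max_n,
         call. = FALSE)
  }
  # pair sets over [i, j) as 2-column matrices
  rec <- function(i, j) {
    if (j - i <= 1L) return(list(matrix(integer(0), ncol = 2L)))
    out <- rec(i, j - 1L)  # last base unpaired
    for (a in i:(j - 2L)) {
      if (!.comp_chr(ch[a + 1L], ch[j])) next
      left <- rec(i, a)
      inner <- rec(a + 1L, j - 1L)
      for (fl in left) for (fi in inner) {
        out[[length(out) + 1L]] <- rbind(fl, fi, c(a, j - 1L))
      }
    }
    out
  }
  lapply(rec(0L, n), folding, n = n)
}

#' Brute-force RNA folding quantities by enumeration
#'
#' `brute_max_pairs` returns the maximum complementary pair count,
#' `brute_partition` the partition function \eqn{Z = \sum_F e^{|F|}}, and
#' `brute_bpp` the full matrix of base-pair probabilities
#' \eqn{P(a\cdot b) = \sum_{F \ni a\cdot b} e^{|F|} / Z}, all by direct
#' enumeration of the nested foldings.
#'
#' @param s RNA string (guarded length).
#' @param max_n length guard.
#' @return see above; `brute_bpp` returns an `n x n` matrix with
#'   `[a+1, b+1]` the probability of pairing bases `a` and `b` (0-based).
#' @export
brute_max_pairs <- function(s, max_n = 14L) {
  fs <- enumerate_foldings(s, max_n)
  max(vapply(fs, function(f) nrow(f$pairs), integer(1)))
}

#' @rdname brute_max_pairs
#' @export
brute_partition <- function(s, max_n = 14L) {
  fs <- enumerate_foldings(s, max_n)
  sum(vapply(fs, function(f) exp(nrow(f$pairs)), numeric(1)))
}

#' @rdname brute_max_pairs
#' @export
brute_bpp <- function(s, max_n = 14L) {
  s <- normalize_rna(s)
  n <- nchar(s)
  fs <- enumerate_foldings(s, max_n)
  W <- matrix(0, n, n)
  Z <- 0
  for (f in fs) {
    w <- exp(nrow(f$pairs))
    Z <- Z + w
    p <- f$pairs
    if (nrow(p)) {
      for (r in seq_len(nrow(p))) {
        W[p[r, 1] + 1L, p[r, 2] + 1L] <- W[p[r, 1] + 1L, p[r, 2] + 1L] + w
      }
    }
  }
  W / Z
}

#' Naive CKY recognition and best-parse weight
#'
#' Plain triple-loop CKY over a [cnf_grammar]: boolean recognition
#' (`brute_cfg`) and max-plus best-parse weight (`brute_wcfg`, the weight
#' of a parse being the sum over all rule applications, terminal rules
#' included; `-Inf` when unparseable).  Independent of the engine code.
#'
#' @param g a [cnf_grammar].
#' @param tokens character vector of terminals.
#' @param max_n sentence-length guard.
#' @export
brute_cfg <- function(g, tokens, max_n = 20L) {
  n <- length(tokens)
  if (n > max_n) stop("brute_cfg: guard exceeded", call. = FALSE)
  if (n == 0L) return(FALSE)
  nts <- g$nonterminals
  K <- length(nts)
  # tab[[A]][i, j]: TRUE iff A derives tokens (i, j] ... 0-based positions
  tab <- lapply(seq_len(K), function(k) matrix(FALSE, n + 1L, n + 1L))
  names(tab) <- nts
  for (i in seq_len(n)) {
    hits <- g$terminal_rules$lhs[g$terminal_rules$token == tokens[i]]
    for (A in hits) tab[[A]][i, i + 1L] <- TRUE
  }
  if (n >= 2L) {
    for (span in 2:n) {
      for (i in 0:(n - span)) {
        j <- i + span
        for (r in seq_len(nrow(g$binary_rules))) {
          A <- g$binary_rules$lhs[r]
          Bs <- g$binary_rules$rhs1[r]
          Cs <- g$binary_rules$rhs2[r]
          for (q in (i + 1L):(j - 1L)) {
            if (tab[[Bs]][i + 1L, q + 1L] && tab[[Cs]][q + 1L, j + 1L]) {
              tab[[A]][i + 1L, j + 1L] <- TRUE
              break
            }
          }
        }
      }
    }
  }
  tab[[g$start]][1L, n + 1L]
}

#' @rdname brute_cfg
#' @export
brute_wcfg <- function(g, tokens, max_n = 20L) {
  n <- length(tokens)
  if (n > max_n) stop("brute_wcfg: guard exceeded", call. = FALSE)
  if (n == 0L) return(-Inf)
  nts <- g$nonterminals
  K <- length(nts)
  tab <- lapply(seq_len(K), function(k) matrix(-Inf, n + 1L, n + 1L))
  names(tab) <- nts
  tr <- g$terminal_rules
  for (i in seq_len(n)) {
    for (r in seq_len(nrow(tr))) {
      if (tr$token[r] == tokens[i]) {
        A <- tr$lhs[r]
        tab[[A]][i, i + 1L] <- max(tab[[A]][i, i + 1L], tr$weight[r])
      }
    }
  }
  br <- g$binary_rules
  if (n >= 2L) {
    for (span in 2:n) {
      for (i in 0:(n - span)) {
        j <- i + span
        for (r in seq_len(nrow(br))) {
          A <- br$lhs[r]
          best <- tab[[A]][i + 1L, j + 1L]
          for (q in (i + 1L):(j - 1L)) {
            cand <- br$weight[r] + tab[[br$rhs1[r]]][i + 1L, q + 1L] +
              tab[[br$rhs2[r]]][q + 1L, j + 1L]
            if (cand > best) best <- cand
          }
          tab[[A]][i + 1L, j + 1L] <- best
        }
      }
    }
  }
  tab[[g$start]][1L, n + 1L]
}

#' Brute-force simultaneous alignment and folding score
#'
#' Plain memoized recursion over the position lattice, evaluating the
#' alignment-with-folding recurrence directly (no engine code, no matrix
#' products).  Guarded by the lattice size.
#'
#' @param S a [multistring_instance].
#' @param scoring a [saf_scoring].
#' @param max_cells guard on the number of lattice positions.
#' @return the optimal alignment-with-folding score.
#' @export
brute_saf <- function(S, scoring, max_cells = 2500L) {
  codec <- position_codec(S$lengths)
  if (codec$size > max_cells) {
    stop("brute_saf: lattice size ", codec$size, " exceeds guard ", max_cells,
         call. = FALSE)
  }
  chars <- lapply(S$strings, function(s) strsplit(s, "")[[1]])
  memo <- new.env(parent = emptyenv())
  col_of <- function(Q, Q2) .saf_column(chars, Q, Q2)
  sc <- function(X, Y) {
    key <- paste(c(X, Y), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (all(X == Y)) { memo[[key]] <- 0; return(0) }
    best <- -Inf
    if (all(Y - X <= 1L)) best <- scoring$rho(col_of(X, Y))  # single column
    for (Xp in local_increments(X, codec)) {
      if (!position_leq(Xp, Y)) next
      for (Yp in local_decrements(Y, codec)) {
        if (!position_leq(X, Yp) || !position_leq(Xp, Yp)) next
        inner <- sc(Xp, Yp)
        if (inner == -Inf) next
        cand <- inner + scoring$rho(col_of(X, Xp)) + scoring$rho(col_of(Yp, Y)) +
          scoring$tau(col_of(X, Xp), col_of(Yp, Y))
        if (cand > best) best <- cand
      }
    }
    i <- codec_encode(X, codec); j <- codec_encode(Y, codec)
    if (j - i >= 2L) {
      for (q in (i + 1L):(j - 1L)) {
        Q <- codec_decode(q, codec)
        if (!position_leq(X, Q) || !position_leq(Q, Y)) next
        if (all(Q == X) || all(Q == Y)) next
        cand <- sc(X, Q) + sc(Q, Y)
        if (cand > best) best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  sc(rep(0L, codec$m), S$lengths)
}
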
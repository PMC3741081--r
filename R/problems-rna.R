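#' RNA alphabet handling and base complementarity
#'
#' Sequences are normalized to the RNA alphabet `A`, `C`, `G`, `U`:
#' lowercase is folded to uppercase and `T` is mapped to `U`; any other
#' character is an error.  Complementary pairs are A-U, C-G and the G-U
#' wobble pair.
#'
#' @param s character scalar (a raw sequence).
#' @return `normalize_rna` returns the normalized sequence;
#'   `complementary` returns a logical.
#' @export
normalize_rna <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- chartr("acgut", "ACGUU", s)
  s <- chartr("T", "U", s)
  bad <- setdiff(strsplit(s, "")[[1]], c("A", "C", "G", "U"))
  if (length(bad)) {
    stop("non-RNA residue(s) in sequence: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  s
}

#' @rdname normalize_rna
#' @param x,y single bases in `A`, `C`, `G`, `U`.
#' @examples
#' complementary("G", "U")  # TRUE (wobble)
#' complementary("A", "C")  # FALSE
#' @export
complementary <- function(x, y) {
  if (!all(c(x, y) %in% c("A", "C", "G", "U"))) {
    stop("complementary() expects RNA bases, got ", x, ", ", y, call. = FALSE)
  }
  p <- paste0(x, y)
  p %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

.rna_chars <- function(s) strsplit(normalize_rna(s), "")[[1]]

# complementarity indicator over character vectors (no error checking;
# callers have normalized)
.comp_chr <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

#' Nested foldings (secondary structures)
#'
#' A folding of a string of length `n` is a set of index pairs `a.b`
#' (`0 <= a < b < n`) with no two distinct pairs `a.b`, `c.d` satisfying
#' `a <= c <= b <= d` — i.e. pairs are nested, never crossing.
#'
#' @param pairs two-column integer matrix (possibly 0-row) of 0-based index
#'   pairs, first column strictly less than second.
#' @param n string length the folding refers to.
#' @return object of class `folding`.
#' @export
folding <- function(pairs, n) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs)) {
    stopifnot(all(pairs[, 1] < pairs[, 2]), all(pairs >= 0L),
              all(pairs[, 2] < n))
  }
  f <- structure(list(pairs = pairs, n = as.integer(n)), class = "folding")
  if (!is_nested(f)) stop("crossing base pairs in folding", call. = FALSE)
  f
}

#' @rdname folding
#' @param f a `folding`.
#' @export
is_nested <- function(f) {
  p <- f$pairs
  m <- nrow(p)
  if (m < 2L) return(TRUE)
  for (u in seq_len(m - 1L)) {
    for (w in (u + 1L):m) {
      a <- p[u, 1]; b <- p[u, 2]; cc <- p[w, 1]; d <- p[w, 2]
      if ((a <= cc && cc <= b && b <= d) || (cc <= a && a <= d && d <= b)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' @export
print.folding <- function(x, ...) {
  cat("<folding of", x$n, "bases,", nrow(x$pairs), "pairs>\n")
  if (nrow(x$pairs)) {
    cat(paste0(x$pairs[, 1], "*", x$pairs[, 2], collapse = " "), "\n")
  }
  invisible(x)
}

# --- base-pair maximization --------------------------------------------

#' Base-pair maximization problem
#'
#' The inside property \eqn{\beta_{i,j}} is the maximum number of
#' complementary base pairs over all nested foldings of the substring
#' between positions `i` and `j`.  Base cases
#' \eqn{\beta_{i,i} = \beta_{i,i+1} = 0}; otherwise
#' \deqn{\beta_{i,j} = \max\{\beta_{i+1,j-1} + \delta_{i,j-1},\;
#'   \max_{q \in (i,j)} (\beta_{i,q} + \beta_{q,j})\}}
#' with \eqn{\delta = 1} iff the closing bases are complementary — a
#' max-plus problem with a single property and a single split slot.
#'
#' @param s RNA string.
#' @return `bp_max_spec` returns the [inside_spec]; `fold_max_pairs` the
#'   optimal pair count \eqn{\beta_{0,n}} (an integer-valued double).
#' @examples
#' fold_max_pairs("ACAGUGACU")  # 3
#' @export
bp_max_spec <- function(s) {
  ch <- .rna_chars(s)
  v <- standard_variants()$max_plus
  finalize <- function(i, j, mu, read) {
    if (j <= i + 1L) return(0)
    delta <- if (.comp_chr(ch[i + 1L], ch[j])) 1 else 0  # bases s_i, s_{j-1}
    max(read(1L, i + 1L, j - 1L) + delta, mu[[1L]][1L])
  }
  inside_spec(1L, v, list(list(c(1L, 1L))), finalize)
}

#' @rdname bp_max_spec
#' @param kernel,cutoff passed to [run_inside()].
#' @export
fold_max_pairs <- function(s, kernel = "default", cutoff = 32L) {
  s <- normalize_rna(s)
  N <- nchar(s) + 1L
  B <- run_inside(N, bp_max_spec(s), kernel = kernel, cutoff = cutoff)
  B$beta1[1L, N]
}

#' Recover one optimal folding from a filled base-pair matrix
#'
#' Deterministic traceback over the base-pair maximization matrix: when the
#' closing pair is complementary and accounts for the cell's value it is
#' taken; otherwise the smallest split point that reproduces the value is
#' used.  The returned folding is nested and rescoring it yields
#' \eqn{\beta_{0,n}}.
#'
#' @param s RNA string.
#' @param B optional `beta` matrix from [run_inside()] with [bp_max_spec()]
#'   (recomputed when missing).
#' @return a [folding].
#' @export
traceback_max_pairs <- function(s, B = NULL) {
  s <- normalize_rna(s)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  N <- n + 1L
  if (is.null(B)) B <- run_inside(N, bp_max_spec(s))$beta1
  pairs <- matrix(integer(0), ncol = 2L)
  tb <- function(i, j) {
    if (j <= i + 1L) return(invisible(NULL))
    val <- B[i + 1L, j + 1L]
    comp <- .comp_chr(ch[i + 1L], ch[j])
    if (comp && val == B[i + 2L, j] + 1) {
      pairs <<- rbind(pairs, c(i, j - 1L))
      tb(i + 1L, j - 1L)
      return(invisible(NULL))
    }
    for (q in (i + 1L):(j - 1L)) {
      if (val == B[i + 1L, q + 1L] + B[q + 1L, j + 1L]) {
        tb(i, q); tb(q, j)
        return(invisible(NULL))
      }
    }
    stop("inconsistent base-pair matrix at [", i, ",", j, "]", call. = FALSE)
  }
  tb(0L, n)
  folding(pairs, n)
}

#' Score a folding by its complementary pair count
#'
#' @param f a [folding].
#' @param s the RNA string it refers to.
#' @return number of complementary pairs in `f`.
#' @export
count_complementary_pairs <- function(f, s) {
  ch <- .rna_chars(s)
  p <- f$pairs
  if (!nrow(p)) return(0L)
  sum(.comp_chr(ch[p[, 1] + 1L], ch[p[, 2] + 1L]))
}

# --- simplified partition function -------------------------------------

#' Simplified Boltzmann partition function for nested RNA foldings
#'
#' Each folding `F` over complementary pairs is weighted `exp(|F|)`; the
#' partition function `Z` is the sum of weights over all nested foldings.
#' Two mutually recursive inside properties are used: `beta1[i,j]`, the
#' weight sum of foldings of the substring that contain the closing pair
#' `i.(j-1)`, and `beta2[i,j]`, the full weight sum (the substring's
#' partition function):
#' \deqn{\beta^1_{i,j} = \delta_{i,j-1}\,\beta^2_{i+1,j-1}, \quad
#'   \beta^2_{i,j} = \mu^2_{i,j} + \beta^2_{i,j-1} + \beta^1_{i,j}}
#' with \eqn{\mu^2_{i,j} = \sum_{q\in(i,j)} \beta^2_{i,q}\,\beta^1_{q,j}}
#' and \eqn{\delta = e} for complementary closing bases, else 0.  Base
#' cases: `beta1 = 0`, `beta2 = 1` for `j <= i + 1`.  A dot-product
#' problem; weights grow like `exp(n/2)`, so very long strings will
#' overflow double precision (a warning is raised past the documented
#' range).
#'
#' @param s RNA string.
#' @return `partition_spec` returns the [inside_spec];
#'   `partition_function` a list with elements `Z`, `beta1`, `beta2`.
#' @examples
#' partition_function("AU")$Z  # 1 + e
#' @export
partition_spec <- function(s) {
  ch <- .rna_chars(s)
  v <- standard_variants()$dot
  finalize <- function(i, j, mu, read) {
    if (j <= i + 1L) return(c(0, 1))
    delta <- if (.comp_chr(ch[i + 1L], ch[j])) exp(1) else 0
    b1 <- delta * read(2L, i + 1L, j - 1L)
    b2 <- mu[[2L]][1L] + read(2L, i, j - 1L) + b1
    c(b1, b2)
  }
  inside_spec(2L, v, list(list(), list(c(2L, 1L))), finalize)
}

#' @rdname partition_spec
#' @param kernel,cutoff passed to [run_inside()].
#' @export
partition_function <- function(s, kernel = "default", cutoff = 32L) {
  s <- normalize_rna(s)
  n <- nchar(s)
  if (n > 600L) {
    warning("partition weights may overflow double precision for n > ~600",
            call. = FALSE)
  }
  N <- n + 1L
  B <- run_inside(N, partition_spec(s), kernel = kernel, cutoff = cutoff)
  list(Z = B$beta2[1L, N], beta1 = B$beta1, beta2 = B$beta2)
}

# --- base-pair binding probabilities (inside-outside) ------------------

# weight of closing bases a, b (0-based indices into the string): e when
# complementary, 0 otherwise or when an index is out of range
.delta_e <- function(ch, a, b) {
  n <- length(ch)
  if (a < 0L || b < 0L || a >= n || b >= n) return(0)
  if (.comp_chr(ch[a + 1L], ch[b + 1L])) exp(1) else 0
}

#' Base-pair binding probabilities via the outside engine
#'
#' Given the partition-function inside matrices (see [partition_spec()]),
#' four mutually recursive outside properties of the residual string
#' (prefix before `i` plus suffix from `j`) are computed:
#' `alpha1` (weight sum of residual foldings containing the pair
#' `(i-1).j`), `alpha2` (containing a pair `(q-1).j` for some `q < i`,
#' a prefix-form split over `beta2` and `alpha1`), `alpha3` (containing a
#' pair `j.(q-1)` for some `q > j`, a suffix-form split over `alpha4` and
#' `beta1`), and `alpha4` (the residual's partition function,
#' `alpha4[i,j] = alpha4[i,j+1] + alpha1 + alpha2 + alpha3`).  At the
#' right boundary `j = n` the residual degenerates to the prefix alone,
#' so `alpha4[i,n] = beta2[0,i]` and the pair-containing sets are empty.
#'
#' The weight sum of whole-string foldings containing the pair `i.(j-1)`
#' is then `gamma[i,j] = beta1[i,j] * alpha4[i,j]`, and
#' `P(a.b) = gamma[a, b+1] / Z`.
#'
#' @param s RNA string.
#' @return `bpp_spec` returns the [outside_spec];
#'   `base_pair_probabilities` a list with the `n x n` probability matrix
#'   `P` (`[a+1, b+1]` the probability of pairing bases `a` and `b`),
#'   `gamma`, `Z`, and the four outside matrices.
#' @examples
#' base_pair_probabilities("AU")$P[1, 2]  # e / (1 + e)
#' @export
bpp_spec <- function(s) {
  ch <- .rna_chars(s)
  n <- length(ch)
  v <- standard_variants()$dot
  finalize <- function(i, j, mu, read_alpha, read_beta) {
    if (j == n) {
      return(c(0, 0, 0, read_beta(2L, 0L, i)))
    }
    a1 <- .delta_e(ch, i - 1L, j) * read_alpha(4L, i - 1L, j + 1L)
    a2 <- mu[2L]
    a3 <- mu[3L]
    a4 <- read_alpha(4L, i, j + 1L) + a1 + a2 + a3
    c(a1, a2, a3, a4)
  }
  outside_spec(
    4L, v,
    list(NULL,
         list(form = "prefix", k_beta = 2L, k_alpha = 1L),
         list(form = "suffix", k_beta = 1L, k_alpha = 4L),
         NULL),
    finalize)
}

#' @rdname bpp_spec
#' @param kernel,cutoff passed to the engines.
#' @export
base_pair_probabilities <- function(s, kernel = "default", cutoff = 32L) {
  s <- normalize_rna(s)
  n <- nchar(s)
  N <- n + 1L
  inside <- run_inside(N, partition_spec(s), kernel = kernel, cutoff = cutoff)
  outside <- run_outside(inside, bpp_spec(s), kernel = kernel, cutoff = cutoff)
  Z <- inside$beta2[1L, N]
  stopifnot(Z >= 1)  # the empty folding always contributes weight 1
  gamma <- inside$beta1 * outside$alpha4
  P <- matrix(0, n, n)
  if (n >= 2L) {
    for (a in 0:(n - 2L)) {
      for (b in (a + 1L):(n - 1L)) {
        P[a + 1L, b + 1L] <- gamma[a + 1L, b + 2L] / Z
      }
    }
  }
  list(P = P, gamma = gamma, Z = Z, outside = outside, inside = inside)
}
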
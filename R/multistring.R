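#' Multiple-string instances and the mixed-radix position codec
#'
#' A multiple-string instance is an ordered set of strings
#' `s^0 .. s^(m-1)`.  A position is an m-tuple of per-string indices
#' `X = (i_0, ..., i_(m-1))` with `0 <= i_p <= n_p`; the lattice of
#' positions has size `||S|| = prod(n_p + 1)`.  The codec linearizes
#' positions mixed-radix with string 0 as the least significant digit:
#' `h(X) = sum_p i_p * prod_{p' < p} (n_{p'} + 1)`, a bijection onto
#' `0..||S||-1` that is monotone for the componentwise order
#' (`X <= Y  =>  h(X) <= h(Y)`, but not conversely).
#'
#' @param strings character vector of RNA strings (normalized on input).
#' @return `multistring_instance` returns an object with elements
#'   `strings`, `lengths`, `m`, `size`.
#' @export
multistring_instance <- function(strings) {
  stopifnot(length(strings) >= 1L)
  strings <- vapply(strings, normalize_rna, character(1), USE.NAMES = FALSE)
  lens <- nchar(strings)
  structure(list(strings = strings, lengths = as.integer(lens),
                 m = length(strings),
                 size = prod(as.double(lens) + 1)),
            class = "multistring_instance")
}

#' @rdname multistring_instance
#' @param lengths integer vector of string lengths `n_p` (strings of
#'   length 0 are allowed: radix 1).
#' @return `position_codec` returns a codec with `radices`, `weights`,
#'   `m` and `size`.
#' @export
position_codec <- function(lengths) {
  lengths <- as.integer(lengths)
  stopifnot(length(lengths) >= 1L, all(lengths >= 0L))
  radices <- lengths + 1L
  weights <- cumprod(c(1, as.double(radices[-length(radices)])))
  structure(list(lengths = lengths, radices = radices, weights = weights,
                 m = length(lengths), size = prod(as.double(radices))),
            class = "position_codec")
}

#' Encode and decode positions
#'
#' @param X integer position tuple.
#' @param codec a [position_codec].
#' @return `codec_encode` the 0-based linear index; `codec_decode` the
#'   position tuple.
#' @examples
#' cd <- position_codec(c(3, 3))
#' codec_encode(c(1, 2), cd)  # 1 + 2*4 = 9
#' @export
codec_encode <- function(X, codec) {
  stopifnot(length(X) == codec$m)
  if (any(X < 0L) || any(X > codec$lengths)) {
    stop("position component out of range: (", paste(X, collapse = ","), ")",
         call. = FALSE)
  }
  as.integer(sum(X * codec$weights))
}

#' @rdname codec_encode
#' @param i 0-based linear index in `[0, size)`.
#' @export
codec_decode <- function(i, codec) {
  stopifnot(i >= 0, i < codec$size)
  X <- integer(codec$m)
  for (p in seq_len(codec$m)) {
    X[p] <- i %% codec$radices[p]
    i <- i %/% codec$radices[p]
  }
  X
}

#' Componentwise position order
#'
#' `X <= Y` iff every component of `X` is at most the matching component
#' of `Y`.  Note this is a partial order: `h(X) <= h(Y)` does not imply
#' `position_leq(X, Y)`.
#'
#' @param X,Y position tuples of equal arity.
#' @return logical scalar.
#' @export
position_leq <- function(X, Y) {
  if (length(X) != length(Y)) stop("position arity mismatch", call. = FALSE)
  all(X <= Y)
}

#' Local increments and decrements of a position
#'
#' A local increment of `Q` adds 0 or 1 to each component (not all zero),
#' keeping every component within its string's range; it corresponds to
#' appending one alignment column.  Local decrements are symmetric.  Each
#' set has at most `2^m - 1` elements.
#'
#' @param X position tuple.
#' @param codec a [position_codec].
#' @return list of position tuples (possibly empty).
#' @export
local_increments <- function(X, codec) {
  m <- codec$m
  deltas <- as.matrix(expand.grid(rep(list(0:1), m)))[-1L, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(deltas))) {
    Y <- X + deltas[r, ]
    if (all(Y <= codec$lengths)) out[[length(out) + 1L]] <- as.integer(Y)
  }
  out
}

#' @rdname local_increments
#' @param Y position tuple.
#' @export
local_decrements <- function(Y, codec) {
  m <- codec$m
  deltas <- as.matrix(expand.grid(rep(list(0:1), m)))[-1L, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(deltas))) {
    X <- Y - deltas[r, ]
    if (all(X >= 0L)) out[[length(out) + 1L]] <- as.integer(X)
  }
  out
}

#' Run the inside engine over a multiple-string position lattice
#'
#' Reduces an inside problem over m-tuples of positions to the single
#' index space `0..||S||-1` through the codec: matrix cell `(h(X), h(Y))`
#' holds the property of sub-instance `S[X,Y]`, cells whose decoded
#' positions are not componentwise ordered are masked and stay `phi` —
#' masked factors then contribute `phi` to every split product, which is
#' exactly why the linearized engine computes the lattice recurrence.  The
#' variant's `oplus` must be commutative: the lattice split points carry
#' no natural left-to-right order.
#'
#' @param S a [multistring_instance].
#' @param spec an [inside_spec] whose `finalize` interprets indices through
#'   the same codec (see [saf_spec()]).
#' @param kernel,cutoff,verify passed to [run_inside()].
#' @param max_size refuse lattices larger than this (dense `||S|| x ||S||`
#'   matrices are allocated).
#' @return named list of property matrices of shape `||S|| x ||S||`.
#' @export
run_multistring_inside <- function(S, spec, kernel = "default", cutoff = 32L,
                                   verify = FALSE, max_size = 4096L) {
  stopifnot(inherits(S, "multistring_instance"), inherits(spec, "inside_spec"))
  if (!spec$variant$oplus_commutative) {
    stop("the multiple-string reduction requires a commutative oplus",
         call. = FALSE)
  }
  codec <- position_codec(S$lengths)
  if (codec$size > max_size) {
    stop("lattice size ", codec$size, " exceeds the memory cap ", max_size,
         " (dense matrices of that order would be allocated)", call. = FALSE)
  }
  N <- as.integer(codec$size)
  # decode once; mask = componentwise comparability of decoded endpoints
  pos <- vapply(0:(N - 1L), codec_decode, integer(codec$m), codec = codec)
  pos <- matrix(pos, nrow = codec$m)
  user_valid <- spec$cell_valid
  mask_valid <- function(i, j) {
    ok <- all(pos[, i + 1L] <= pos[, j + 1L])
    if (ok && !is.null(user_valid)) ok <- user_valid(i, j)
    ok
  }
  spec2 <- inside_spec(spec$K, spec$variant, spec$mu_specs, spec$finalize,
                       spec$property_names, cell_valid = mask_valid)
  run_inside(N, spec2, kernel = kernel, cutoff = cutoff, verify = verify)
}
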
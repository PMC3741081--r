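# Seeded random generators for test fixtures: uniform RNA strings, CNF
# grammars with guaranteed terminal coverage, and multiple-string
# instances.  Deterministic under a given seed.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Seeded random fixtures
#'
#' `gen_random_rna` draws bases uniformly; `gen_random_cnf` builds a CNF
#' grammar in which every nonterminal owns at least one terminal rule (so
#' nonempty languages occur with useful frequency) plus `n_rules` random
#' binary rules; `gen_random_multistring` draws one RNA string per
#' requested length.  All are deterministic under `seed`.
#'
#' @param length number of bases.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return `gen_random_rna`: a character scalar (possibly empty).
#' @export
gen_random_rna <- function(length, seed = NULL) {
  stopifnot(length >= 0L)
  .with_seed(seed, {
    if (length == 0L) "" else
      paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
            collapse = "")
  })
}

#' @rdname gen_random_rna
#' @param n_nonterminals,n_rules grammar size (binary rule count).
#' @param alphabet terminal alphabet.
#' @param weight_range range for rule weights.  Weights are drawn on a
#'   dyadic grid (multiples of 1/64) so that parse-weight sums are exact in
#'   binary floating point and independent evaluation orders compare
#'   exactly.
#' @return `gen_random_cnf`: a [cnf_grammar].
#' @export
gen_random_cnf <- function(n_nonterminals, n_rules,
                           alphabet = c("a", "b", "c"), seed = NULL,
                           weight_range = c(-1, 2)) {
  stopifnot(n_nonterminals >= 1L, n_rules >= 0L)
  wgrid <- seq(weight_range[1], weight_range[2], by = 1 / 64)
  .with_seed(seed, {
    nts <- paste0("N", seq_len(n_nonterminals))
    nts[1] <- "S"
    term <- data.frame(
      lhs = c(nts, sample(nts, max(0L, n_nonterminals %/% 2L), replace = TRUE)),
      stringsAsFactors = FALSE)
    term$token <- sample(alphabet, nrow(term), replace = TRUE)
    term$weight <- sample(wgrid, nrow(term), replace = TRUE)
    if (n_rules > 0L) {
      bin <- data.frame(
        lhs = sample(nts, n_rules, replace = TRUE),
        rhs1 = sample(nts, n_rules, replace = TRUE),
        rhs2 = sample(nts, n_rules, replace = TRUE),
        weight = sample(wgrid, n_rules, replace = TRUE),
        stringsAsFactors = FALSE)
    } else {
      bin <- data.frame(lhs = character(0), rhs1 = character(0),
                        rhs2 = character(0), weight = numeric(0))
    }
    cnf_grammar(bin, term, start = "S")
  })
}

#' @rdname gen_random_rna
#' @param lengths integer vector of per-string lengths.
#' @return `gen_random_multistring`: a [multistring_instance].
#' @export
gen_random_multistring <- function(lengths, seed = NULL) {
  .with_seed(seed, {
    multistring_instance(vapply(lengths, function(n) gen_random_rna(n),
                                character(1)))
  })
}
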
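#' Read RNA sequences from a FASTA file
#'
#' Parses with Biostrings and normalizes each record to the RNA alphabet
#' (case folded, `T` mapped to `U`); any other residue is an error.
#' Multi-record files are allowed — the records of one file form the
#' instance for simultaneous alignment and folding.
#'
#' @param path FASTA file.
#' @return named character vector of sequences (names from the headers).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- vapply(as.character(set), normalize_rna, character(1))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write base-pair probabilities as TSV
#'
#' One row per base pair `a < b`, columns `i`, `j` (1-based inclusive base
#' indices) and `prob` with nine significant digits.
#'
#' @param path output file.
#' @param P probability matrix from [base_pair_probabilities()].
#' @param min_prob rows with smaller probability are omitted (0 keeps all).
#' @export
write_bpp <- function(path, P, min_prob = 0) {
  n <- nrow(P)
  rows <- list("i\tj\tprob")
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        if (P[a, b] >= min_prob) {
          rows[[length(rows) + 1L]] <- sprintf("%d\t%d\t%.9g", a, b, P[a, b])
        }
      }
    }
  }
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Render a folding in dot-bracket notation
#'
#' One character per base: `(` and `)` for the two sides of a pair, `.`
#' for unpaired bases.  The folding must be nested (crossing pairs cannot
#' be rendered and raise an error).
#'
#' @param f a [folding] (or a 2-column 0-based pair matrix).
#' @param n number of bases; defaults to `f$n`.
#' @return character scalar of length-`n`.
#' @examples
#' render_dotbracket(folding(rbind(c(0, 1)), 2))  # "()"
#' @export
render_dotbracket <- function(f, n = NULL) {
  if (!inherits(f, "folding")) f <- folding(f, n)
  if (is.null(n)) n <- f$n
  out <- rep(".", n)
  p <- f$pairs
  if (nrow(p)) {
    out[p[, 1] + 1L] <- "("
    out[p[, 2] + 1L] <- ")"
  }
  paste(out, collapse = "")
}

#' @rdname render_dotbracket
#' @param path output file.
#' @export
write_dotbracket <- function(path, f, n = NULL) {
  writeLines(render_dotbracket(f, n), path)
  invisible(path)
}

#' Parse dot-bracket notation back into a folding
#'
#' @param x dot-bracket string.
#' @return a [folding].
#' @export
parse_dotbracket <- function(x) {
  ch <- strsplit(x, "")[[1]]
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k - 1L)
    } else if (ch[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
      pairs <- rbind(pairs, c(stack[length(stack)], k - 1L))
      stack <- stack[-length(stack)]
    } else if (ch[k] != ".") {
      stop("unexpected character in dot-bracket string: ", ch[k], call. = FALSE)
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
  folding(pairs, length(ch))
}

#' Run configuration
#'
#' Bundles the tunable run parameters shared by the user-facing functions
#' and the command-line interface.  Identical configuration and inputs
#' give bit-identical outputs for the discrete domains.
#'
#' @param kernel kernel name used for block products.
#' @param cutoff recursion cutoff (>= 1); results are invariant to it.
#' @param verify enable engine pre-condition assertions (small inputs).
#' @param seed optional integer seed for the generators.
#' @param scoring a [saf_scoring] for alignment-with-folding runs.
#' @param max_size memory cap on the multiple-string lattice size.
#' @param log_level one of `"quiet"`, `"info"`, `"debug"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(kernel = "default", cutoff = 32L, verify = FALSE,
                       seed = NULL, scoring = saf_scoring(),
                       max_size = 4096L, log_level = "info") {
  stopifnot(cutoff >= 1L, log_level %in% c("quiet", "info", "debug"))
  structure(list(kernel = kernel, cutoff = as.integer(cutoff),
                 verify = isTRUE(verify),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 scoring = scoring, max_size = as.integer(max_size),
                 log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any of the scalar fields of `run_config`
#'   (`kernel`, `cutoff`, `verify`, `seed`, `max_size`, `log_level`, and
#'   the six constants of [saf_scoring()] under `scoring:`).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- do.call(saf_scoring, if (is.null(y$scoring)) list() else y$scoring)
  run_config(kernel = y$kernel %||% "default",
             cutoff = y$cutoff %||% 32L,
             verify = y$verify %||% FALSE,
             seed = y$seed,
             scoring = sc,
             max_size = y$max_size %||% 4096L,
             log_level = y$log_level %||% "info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
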
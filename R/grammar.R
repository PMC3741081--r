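#' Chomsky-normal-form grammars
#'
#' A CNF grammar has binary rules `A -> B C` and terminal rules
#' `A -> 'a'`, each with an optional real weight (used under max-plus;
#' ignored for boolean recognition).  The rule-file dialect is one rule
#' per line, `LHS -> RHS1 RHS2 [weight]` or `LHS -> 'terminal' [weight]`,
#' `#` comments; the first rule's left-hand side is the start symbol.
#'
#' @param binary_rules data frame with columns `lhs`, `rhs1`, `rhs2`,
#'   `weight`.
#' @param terminal_rules data frame with columns `lhs`, `token`, `weight`.
#' @param start start symbol; defaults to the first binary/terminal LHS.
#' @return object of class `cnf_grammar` with the rule tables, `start`
#'   and the `nonterminals` vector.
#' @export
cnf_grammar <- function(binary_rules, terminal_rules, start = NULL) {
  binary_rules <- as.data.frame(binary_rules, stringsAsFactors = FALSE)
  terminal_rules <- as.data.frame(terminal_rules, stringsAsFactors = FALSE)
  if (!nrow(terminal_rules)) {
    stop("a CNF grammar needs at least one terminal rule", call. = FALSE)
  }
  if (is.null(binary_rules$weight)) binary_rules$weight <- numeric(nrow(binary_rules))
  if (is.null(terminal_rules$weight)) terminal_rules$weight <- numeric(nrow(terminal_rules))
  nts <- unique(c(binary_rules$lhs, terminal_rules$lhs))
  used <- c(binary_rules$rhs1, binary_rules$rhs2)
  undecl <- setdiff(used, nts)
  if (length(undecl)) {
    stop("symbols used on a rule right-hand side but never defined: ",
         paste(undecl, collapse = ", "), call. = FALSE)
  }
  if (is.null(start)) {
    start <- c(binary_rules$lhs, terminal_rules$lhs)[1]
  }
  if (!start %in% nts) stop("start symbol is not a nonterminal", call. = FALSE)
  structure(list(nonterminals = nts, start = start,
                 binary_rules = binary_rules, terminal_rules = terminal_rules),
            class = "cnf_grammar")
}

#' @export
print.cnf_grammar <- function(x, ...) {
  cat(sprintf("<cnf_grammar: %d nonterminals, %d binary + %d terminal rules, start %s>\n",
              length(x$nonterminals), nrow(x$binary_rules),
              nrow(x$terminal_rules), x$start))
  invisible(x)
}

#' @rdname cnf_grammar
#' @param lines character vector of rule lines in the dialect above.
#' @export
parse_grammar <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty grammar", call. = FALSE)
  bin <- list(); term <- list()
  start <- NULL
  for (ln in lines) {
    m <- regmatches(ln, regexec("^(\\S+)\\s*->\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed rule line: ", ln, call. = FALSE)
    lhs <- m[2]
    rhs <- strsplit(trimws(m[3]), "\\s+")[[1]]
    if (is.null(start)) start <- lhs
    w <- 0
    if (length(rhs) && grepl("^[-+]?[0-9.eE+-]+$", rhs[length(rhs)]) &&
        !is.na(suppressWarnings(as.numeric(rhs[length(rhs)])))) {
      w <- as.numeric(rhs[length(rhs)])
      rhs <- rhs[-length(rhs)]
    }
    if (length(rhs) == 1L && grepl("^'.*'$", rhs)) {
      term[[length(term) + 1L]] <- data.frame(
        lhs = lhs, token = sub("^'(.*)'$", "\\1", rhs), weight = w,
        stringsAsFactors = FALSE)
    } else if (length(rhs) == 2L && !any(grepl("^'", rhs))) {
      bin[[length(bin) + 1L]] <- data.frame(
        lhs = lhs, rhs1 = rhs[1], rhs2 = rhs[2], weight = w,
        stringsAsFactors = FALSE)
    } else {
      stop("rule is not in Chomsky normal form: ", ln, call. = FALSE)
    }
  }
  cnf_grammar(
    if (length(bin)) do.call(rbind, bin)
    else data.frame(lhs = character(0), rhs1 = character(0),
                    rhs2 = character(0), weight = numeric(0)),
    do.call(rbind, term), start = start)
}

#' @rdname cnf_grammar
#' @param path rule file path.
#' @export
read_grammar <- function(path) {
  if (!file.exists(path)) stop("grammar file not found: ", path, call. = FALSE)
  parse_grammar(readLines(path, warn = FALSE))
}

#' @rdname cnf_grammar
#' @param g a `cnf_grammar`.
#' @export
write_grammar <- function(g, path) {
  stopifnot(inherits(g, "cnf_grammar"))
  lines <- character(0)
  # keep the start symbol's rules first so round-tripping preserves it
  br <- g$binary_rules; tr <- g$terminal_rules
  ord <- order(c(br$lhs, tr$lhs) != g$start)
  all_lines <- c(
    if (nrow(br)) sprintf("%s -> %s %s %.17g", br$lhs, br$rhs1, br$rhs2, br$weight),
    if (nrow(tr)) sprintf("%s -> '%s' %.17g", tr$lhs, tr$token, tr$weight))
  writeLines(all_lines[ord], path)
  invisible(path)
}

#' Build the CKY inside specification for a grammar and sentence
#'
#' One property per nonterminal (boolean for recognition, max-plus for
#' best-parse weights) and one split slot per binary rule of that symbol;
#' terminal rules seed the length-1 cells inside `finalize`.
#'
#' @param g a [cnf_grammar].
#' @param tokens tokenized sentence.
#' @param weighted `TRUE` for the max-plus (weighted) variant.
#' @return an [inside_spec] with `property_names` the nonterminals.
#' @export
cky_spec <- function(g, tokens, weighted = FALSE) {
  stopifnot(inherits(g, "cnf_grammar"))
  nts <- g$nonterminals
  K <- length(nts)
  idx <- stats::setNames(seq_len(K), nts)
  v <- if (weighted) standard_variants()$max_plus else standard_variants()$boolean
  mu_specs <- vector("list", K)
  slot_w <- vector("list", K)
  br <- g$binary_rules
  for (k in seq_len(K)) {
    rows <- which(br$lhs == nts[k])
    mu_specs[[k]] <- lapply(rows, function(r) c(idx[[br$rhs1[r]]], idx[[br$rhs2[r]]]))
    slot_w[[k]] <- br$weight[rows]
  }
  tr <- g$terminal_rules
  finalize <- function(i, j, mu, read) {
    if (weighted) {
      vals <- numeric(K)
      for (k in seq_len(K)) {
        best <- if (length(mu[[k]])) max(mu[[k]] + slot_w[[k]]) else -Inf
        if (j == i + 1L) {
          hit <- tr$weight[tr$lhs == nts[k] & tr$token == tokens[i + 1L]]
          if (length(hit)) best <- max(best, max(hit))
        }
        vals[k] <- best
      }
    } else {
      vals <- logical(K)
      for (k in seq_len(K)) {
        acc <- any(mu[[k]])
        if (!acc && j == i + 1L) {
          acc <- any(tr$lhs == nts[k] & tr$token == tokens[i + 1L])
        }
        vals[k] <- acc
      }
    }
    vals
  }
  inside_spec(K, v, mu_specs, finalize, property_names = nts)
}

#' CFG recognition and WCFG best-parse weight via the inside engine
#'
#' One boolean (respectively max-plus) inside property per nonterminal:
#' `beta^A[i,j]` states whether (with what best weight) `A` derives the
#' sub-sentence between positions `i` and `j`.  Each binary rule
#' `A -> B C` contributes one split slot `(B, C)`; terminal rules seed the
#' length-1 cells.  The weight of a parse is the sum of the weights of all
#' rule applications, terminal rules included.
#'
#' @param g a [cnf_grammar].
#' @param tokens character vector (a whitespace-tokenized sentence).
#' @param kernel,cutoff passed to [run_inside()].
#' @return `cfg_recognize`: list with `accepted` (logical for the start
#'   symbol over the whole sentence) and the per-nonterminal `matrices`.
#'   `wcfg_best_parse`: the best parse weight (`-Inf` when unparseable).
#' @examples
#' g <- parse_grammar(c("S -> A B", "A -> 'a'", "B -> 'b'"))
#' cfg_recognize(g, c("a", "b"))$accepted  # TRUE
#' @export
cfg_recognize <- function(g, tokens, kernel = "default", cutoff = 32L) {
  stopifnot(inherits(g, "cnf_grammar"))
  n <- length(tokens)
  if (n == 0L) {
    return(list(accepted = FALSE,
                matrices = stats::setNames(
                  lapply(g$nonterminals, function(a) matrix(FALSE, 1, 1)),
                  g$nonterminals)))
  }
  spec <- cky_spec(g, tokens, weighted = FALSE)
  B <- run_inside(n + 1L, spec, kernel = kernel, cutoff = cutoff)
  list(accepted = B[[g$start]][1L, n + 1L], matrices = B)
}

#' @rdname cfg_recognize
#' @export
wcfg_best_parse <- function(g, tokens, kernel = "default", cutoff = 32L) {
  stopifnot(inherits(g, "cnf_grammar"))
  n <- length(tokens)
  if (n == 0L) return(-Inf)
  spec <- cky_spec(g, tokens, weighted = TRUE)
  B <- run_inside(n + 1L, spec, kernel = kernel, cutoff = cutoff)
  B[[g$start]][1L, n + 1L]
}
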
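# shared helpers: seeded fixtures and tolerant comparisons

rand_rna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

rand_matrix <- function(nr, nc, v) {
  switch(v$name,
         boolean = matrix(stats::runif(nr * nc) < 0.4, nr, nc),
         dot = matrix(stats::runif(nr * nc), nr, nc),
         matrix(sample(-5:9, nr * nc, replace = TRUE), nr, nc))
}

rel_close <- function(a, b, tol = 1e-9) {
  if (is.infinite(a) && is.infinite(b)) return(sign(a) == sign(b))
  abs(a - b) <= tol * max(1, abs(a), abs(b))
}

mats_equal <- function(A, B, v, tol = 1e-9) {
  expect_true(matrices_close(A, B, v, tol))
}

rand_sentence <- function(n, alphabet = c("a", "b", "c")) {
  sample(alphabet, n, replace = TRUE)
}
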
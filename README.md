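# valiantdp

Divide-and-conquer dynamic programming over semiring matrix
multiplication, for chart-style problems on strings.

Many classic sequence algorithms — Nussinov-style RNA base-pair
maximization, McCaskill-style partition functions and base-pair
probabilities, CKY parsing of context-free grammars, Sankoff-style
simultaneous alignment and folding — fill a triangular table of values
`beta[i, j]`, one per substring, where the expensive step at each cell is
a split aggregation

```
mu[i, j] = ⊕_{q in (i, j)}  beta[i, q] ⊗ beta[q, j]
```

over an algebra `(D, ⊗, ⊕, φ)` with associative `⊕` and an absorbing zero
`φ` (dot product, min-plus/max-plus, or boolean).  Evaluated cell by cell
this costs Θ(n³).  `valiantdp` instead computes the table by recursive
halving, deferring all split work to *block matrix products* between
sibling recursive calls, so the per-cell work is constant and the total
cost is governed by the matrix-multiplication routine — pluggable through
a kernel registry, with an operation-counting Strassen kernel included to
make the sub-cubic behaviour measurable.  Inside (substring) and outside
(residual-string) engines are provided, plus a mixed-radix position codec
that runs the inside engine over tuples of positions in several strings.

Every engine result is verifiable in-package against independent slow
oracles: classical-order dynamic programs, brute-force folding
enumeration, naive CKY, and a memoized lattice recursion.

## Worked example

```r
library(valiantdp)

s <- "ACAGUGACU"
fold_max_pairs(s)
#> [1] 3
f <- traceback_max_pairs(s)
render_dotbracket(f)
#> [1] "(..((.)))"
```

Three complementary pairs (A·U, G·U and G·C here) is the best any nested
folding of this nine-base string achieves; the dot-bracket line shows one
optimal folding, pairing bases 0·8, 3·7 and 4·6.  The same string under
the simplified Boltzmann model (every folding `F` weighted `e^|F|`):

```r
partition_function(s)$Z
#> [1] 673.9907
round(base_pair_probabilities(s)$P[1, 9], 4)   # bases 0 and 8, 1-based indexing
#> [1] 0.3599
```

`Z` sums the weights of all nested foldings; the pair 0·8 appears in
foldings carrying about 36% of that weight.  Grammar parsing and
multi-sequence alignment-with-folding run through the same engines:

```r
g <- parse_grammar(c("S -> A B 1", "A -> 'a' 2", "B -> 'b' 3"))
cfg_recognize(g, c("a", "b"))$accepted
#> [1] TRUE
wcfg_best_parse(g, c("a", "b"))     # weights of all rule applications
#> [1] 6

saf_score(multistring_instance(c("GGAUCC", "GGUACC")), saf_scoring())
#> [1] 14
```

A command-line wrapper is installed at `inst/cli/valiantdp`
(subcommands `fold`, `partition`, `bpp`, `recognize`, `parse-weight`,
`saf`, `gen`, `selftest`; global flags `--kernel`, `--cutoff`,
`--verify`, `--seed`, `--config`).

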
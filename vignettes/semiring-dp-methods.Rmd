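---
title: "Divide-and-conquer semiring dynamic programming: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divide-and-conquer semiring dynamic programming: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valiantdp)
```

## The problem class

Many chart-style dynamic programs over a string `s` of length `n` fill an
upper-triangular table of *inside* values `beta[i, j]`, one per substring
between positions `i` and `j` (positions are the `n + 1` points between
characters).  The expensive part of each cell is a *split* value

$$\mu_{i,j} \;=\; \bigoplus_{q \in (i,j)} \beta_{i,q} \otimes \beta_{q,j},$$

an aggregation over all ways of cutting the substring in two.  Classical
bottom-up evaluation spends $\Theta(n)$ per cell and $\Theta(n^3)$ overall
— the Nussinov base-pair recursion, McCaskill-style partition functions,
and CKY parsing all have this shape.  The only structure the split step
actually uses is that $(\mathcal{D}, \otimes, \oplus)$ has an associative
$\oplus$ and a zero element $\phi$ that is neutral for $\oplus$ and
absorbing for $\otimes$; distributivity is never needed.  That makes
$\mu$ values entries of matrix products over the corresponding algebra,
and matrix multiplication can be organized much better than one inner
product at a time.

This package implements that organization generically:

* a **variant registry** (`mult_variant()`, `standard_variants()`) for the
  dot-product, min-plus, max-plus and boolean algebras, with pluggable
  multiplication kernels (`register_kernel()`);
* a divide-and-conquer **inside engine** (`run_inside()`) and **outside
  engine** (`run_outside()`) that defer all split work to block matrix
  products and call a problem-supplied `finalize` once per cell;
* a **multiple-string reduction** (`run_multistring_inside()`) that maps
  tuples of positions in several strings onto one index space through a
  mixed-radix codec;
* concrete **problem instantiations**: RNA base-pair maximization, a
  simplified Boltzmann partition function with base-pair binding
  probabilities, CFG/WCFG parsing in Chomsky normal form, and simultaneous
  alignment-and-folding of several RNA sequences;
* slow **classical evaluators and brute-force oracles** against which
  every engine result is tested.

## How the engines work

### Inside recursion

`run_inside()` maintains one `N x N` matrix per property (`N = n + 1`) and
recursively halves index intervals `(I, J)`.  The invariant on entry to a
block is that everything in the enclosing square except the block itself
is finalized, and the block already holds its split contributions from
between-block cut points — accumulated by block products
`B[I, L] %*% B[L, J2]` performed between the two sibling recursive calls.
At a base cell only the cut points inside the current block remain, so the
per-cell work is constant.  Blocks whose largest side is at most `cutoff`
(default 32) are completed by the classical per-cell loop instead of
recursing further; results are invariant to the cutoff, which the test
suite asserts for cutoffs 1, 2, 8 and 32.

Two generalizations beyond the minimal template are deliberate:

* **Several split slots per property.**  A property may list any number of
  `(k', k'')` pairs, each accumulated in its own shadow matrix.  This lets
  CKY keep one property per nonterminal with one slot per binary rule
  instead of one property per rule.  A list of length one reproduces the
  plain template.
* **Arbitrary `N`.**  The halving uses floor splits directly; no padding
  to powers of two is needed.

One variant is shared by all properties of a spec.  Per-property variants
would be a straightforward extension but no shipped instantiation needs
them; this is a documented limitation.

The aggregation order is preserved: block updates append new cut points on
the correct side of the accumulated value and the naive kernel folds the
inner index strictly left-to-right, so the engine remains correct even for
a hypothetical non-commutative `oplus` (all shipped variants are
commutative; kernels that reorder accumulation declare it and are rejected
for non-commutative variants).

### Outside recursion

Outside values `alpha[i, j]` describe the residual string left after
excising the substring — the prefix before `i` plus the suffix from `j`.
Dependencies run outward-in: a cell needs all of its strict super-ranges,
so the recursion starts from the upper-right corner, finishing the
higher-column half (and lower-row half) of each block first.  Each
property carries at most one split form:

* **prefix**: $\mu_{i,j} = \bigoplus_{q \in [0,i)} \beta_{q,i} \otimes \alpha_{q,j}$,
  bridged by `t(B[L, I2]) %*% A[L, J]`;
* **suffix**: $\mu_{i,j} = \bigoplus_{q \in (j,n]} \alpha_{i,q} \otimes \beta_{j,q}$,
  bridged by `A[I, L] %*% t(B[J2, L])`;
* **none**: the property needs only neighbor reads in `finalize`.

`finalize` receives accessors that return `phi` for out-of-range indices,
which keeps boundary recurrences total without special cases in the
engine.  (The one boundary that is not a `phi` read is problem-level: see
the probability section below.)  A multistring outside engine is not
provided: only the inside variant of the lattice reduction is specified
well enough to implement, and nothing in the package needs the outside
one.

### Debug mode

The recursion invariants are the correctness argument, so they are
executable: with `verify = TRUE` (inputs up to `N = 128`) both engines
recompute a classical oracle up front and assert, on entry to every
recursive call, that the finalized region matches it and that the block's
accumulated split values equal the oracle's bridging product.  Finalize
reads are range-checked against the declared dependency regions at the
same time.

## The instantiations

**Base-pair maximization** (max-plus, `K = 1`).  `beta[i, j]` is the
maximum number of complementary base pairs (A-U, C-G, G-U) over nested
foldings of the substring; `beta[i, i] = beta[i, i+1] = 0`, and otherwise
the best of closing the ends (`beta[i+1, j-1] + 1` if complementary) and
the split value.  `traceback_max_pairs()` recovers one optimal folding
deterministically: the closing pair is taken when it is complementary and
explains the cell's value, otherwise the smallest split that does.
(Preferring a *non*-complementary closing pair would be harmless to the
score but would emit junk pairs — `beta[i+1, j-1]` frequently equals
`beta[i, j]` — so the preference is restricted to complementary closings.)

**Partition function** (dot product, `K = 2`).  Every nested folding `F`
over complementary pairs is weighted $e^{|F|}$; `beta2[i, j]` sums the
weights of all foldings of the substring and `beta1[i, j]` those
containing the closing pair.  This is a deliberately simplified Boltzmann
model — a constant reward per pair rather than a nearest-neighbor energy
model — chosen because it exercises the summation (non-optimization)
shape of the computation with minimal bookkeeping.  Pairs between
adjacent bases are allowed, matching the model's definitions exactly;
real RNA tools impose a minimum hairpin loop, which this model does not.
Weights reach $e^{|F|_{\max}}$, so doubles overflow for strings past
roughly 600 bases; `partition_function()` warns there.

**Base-pair probabilities** (dot product, outside `K = 4`).  With `Z`
from the inside phase, four outside properties are computed: `alpha1`
(residual foldings containing the pair `(i-1).j`), `alpha2` (containing
some `(q-1).j`, `q < i`; prefix form over `beta2`, `alpha1`), `alpha3`
(containing some `j.(q-1)`, `q > j`; suffix form over `alpha4`, `beta1`),
and `alpha4` (the residual's partition function), finalized in that order
because `alpha4` reads the other three at the same cell.  At the right
boundary `j = n` the residual degenerates to the prefix alone, so
`alpha4[i, n] = beta2[0, i]` and the pair-containing sums vanish — the
one boundary case the recurrences do not cover by `phi` reads, because the
"j unpaired" term refers to a character that does not exist there.  The
left boundary `i = 0` needs no such case: its recurrence closes with
`alpha4[0, n] = beta2[n, n] = 1` (the empty residual carries exactly the
empty folding).  Then `gamma[i, j] = beta1[i, j] * alpha4[i, j]` and
`P(a.b) = gamma[a, b+1] / Z`.

**CFG / WCFG parsing** (boolean / max-plus, `K` = number of
nonterminals).  Terminal rules seed length-1 cells; each binary rule is
one split slot.  The weight of a parse is the sum of the weights of *all*
rule applications, terminal rules included — the grammar formalism leaves
this open, and counting every application is the convention the naive CKY
oracle shares.  Empty sentences are rejected (no epsilon rules in CNF
here).

**Simultaneous alignment and folding** (max-plus over the position
lattice).  For `m` strings, positions are m-tuples; the codec `h` maps
them mixed-radix (string 0 least significant) onto `0..||S||-1`, where
`||S||` is the product of the `n_p + 1`.  Componentwise order is monotone
under `h`, and every linear index strictly between `h(X)` and `h(Y)` that
does not decode into the lattice interval has a `phi` factor in its split
product, which is exactly why the linearized engine evaluates the lattice
recurrence.  Cells with incomparable decoded endpoints are masked and
stay `phi`; the variant must have commutative aggregation because lattice
split points have no left-to-right order.  Unequal string lengths are
handled directly by the mixed radices.  Lattices are dense
`||S|| x ||S||` matrices, so a configurable cap (default 4096 positions)
refuses accidental blowup for `m >= 3`; empty strings are legal
(radix 1).

The score of an alignment-with-folding is
$\sum_r \rho(A_r) + \sum_{a \cdot b \in F} \tau(A_a, A_b)$ over columns
and paired columns.  The recurrence maximizes a closing term (first and
last columns paired: all combinations of local increments of `X` and
local decrements of `Y`, at most $2^{2m}$, each scored in `O(m)`) and the
lattice split term.  One case is covered by neither as printed: an
alignment consisting of exactly one column, the analogue of the
`beta[i, i+1] = 0` base case of single-string folding.  The finalize
callback and the independent `brute_saf()` oracle both add this
single-column candidate `rho(S[X, Y])` whenever `Y` is a local increment
of `X`; without it every single-character sub-instance scores `-Inf`.

The default column scoring (`saf_scoring()`) is a plain
match/mismatch/gap model with a complementarity bonus for paired columns
(+1 match, -1 mismatch, -2 base-against-gap, 0 gap-gap, +2 complementary
pair, -3 otherwise), all six constants configurable.  It is a documented,
reproducible default for command-line runs, not a tuned biological
scheme; the test suite works with the single-string reduction scoring
(`saf_scoring_fold()`: `rho = 0`, `tau` = +1 for complementary, `-Inf`
otherwise), under which one-string instances reproduce
`fold_max_pairs()` exactly.

## Kernels and numerical choices

The shipped kernels are practical, not asymptotically optimal: the
dot-product kernel is the vendor dense multiply (`%*%`), the boolean
kernel a 0/1 integer multiply thresholded at `> 0` (exact), the tropical
kernels blocked rank-1 updates, and the naive kernel an order-preserving
triple loop used as the agreement oracle for everything else.  The
engine's structure, not the kernel, is the contribution; theoretically
sub-cubic tropical algorithms are out of scope.

A Strassen-style recursive kernel is included for the dot and boolean
variants to make the sub-cubic claim *measurable*: every kernel charges
its scalar-multiplication cost to a global counter
(`mult_op_count()`), dense kernels `n1*n2*n3` per product and the
Strassen kernel only its seven-way recursion's leaf products.  The
recursion falls back to the dense product below a side length of 32 —
small enough that the engine's block products at a few hundred positions
split once or twice, so genuinely fewer scalar multiplications are both
performed and counted at desk scale (the count ratio decreases from
`n = 128` to `n = 256` on the partition-function inside phase).  For the
boolean semiring the Strassen route is exact.  Over floating-point dot
products its subtractive reorganization is accurate relative to the
*block* magnitude, which is the wrong yardstick for Boltzmann matrices
whose entries span `e^0` to `e^|F|max`: small entries lose all relative
accuracy (at `n = 256` the partition function itself is corrupted).  The
Strassen kernel is therefore validated on uniformly scaled random
matrices and used for operation counting and boolean problems, and the
partition-function invariance checks run over the dense and naive
kernels.  This is an inherent property of Strassen-type algorithms on
graded data, not an implementation defect.

Zero elements are native: `-Inf`/`+Inf` for the tropical variants
(`-Inf + x` is `-Inf` natively, keeping kernels vectorizable), `0` for
dot, `FALSE` for boolean.  Cross-implementation comparisons are exact for
the discrete domains and entrywise within `1e-9` relative for dot.  The
random-grammar generator draws rule weights on a dyadic grid (multiples
of 1/64) so that parse-weight sums are exact in double precision no
matter how an evaluator associates the additions; with decimal weights,
independent summation orders differ by an ulp often enough to break exact
cross-oracle equality.

## What the generators emulate, and what they do not

Test inputs are uniform random RNA strings (`gen_random_rna()`), random
CNF grammars in which every nonterminal owns at least one terminal rule
so nonempty languages are frequent (`gen_random_cnf()`), and tuples of
random strings for the lattice problems.  Uniform base composition and
independent positions are adequate for exercising every code path and
every recurrence case of these algorithms, which is what the oracle
suites verify.  They do not emulate biological sequence composition,
codon structure, conserved stems, or natural-language rule distributions
— so passing tests demonstrates algorithmic correctness (engine =
classical DP = enumeration), not predictive quality of the simplified
scoring models on real data.  The problem sizes used by the verification
suites (strings to 64 bases, 200 replicates per problem for the inside
engines; 48 for the outside phase; pairwise lattices to 7x7 positions;
operation counting at 128 and 256 bases) keep the full suite at a few
minutes on one CPU while covering every split-parity and boundary case;
they are the package's chosen study conditions, and the engines
themselves handle any `N` the memory allows.

## Known limitations

* One multiplication variant per problem spec (per-property variants not
  implemented).
* No multistring outside engine; no traceback except for base-pair
  maximization (tracebacks are cheap post-processing and problem-specific).
* The simplified Boltzmann model (constant pair reward, adjacent pairs
  allowed, no minimum loop) is not a thermodynamic folding model.
* Dense matrices throughout; no sparsification of masked lattice cells.
* Partition-function weights overflow doubles for strings much past 600
  bases.
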
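Package: valiantdp
Title: Valiant-Style Dynamic Programming over Semiring Matrix Multiplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generic divide-and-conquer inside and outside dynamic-programming
    engines whose split-combination steps are delegated to pluggable matrix
    multiplication kernels over semiring-like algebras (dot product, min-plus,
    max-plus, boolean). Ships concrete problem instantiations from RNA
    secondary-structure analysis and formal-language parsing: base-pair
    maximization, a simplified Boltzmann partition function with base-pair
    binding probabilities (inside-outside), CFG/WCFG recognition and best-parse
    scoring in Chomsky normal form, and simultaneous alignment-and-folding of
    several RNA sequences via a mixed-radix position encoding. Slow classical
    dynamic programs and brute-force enumeration oracles are included for
    verification, together with seeded random generators for sequences and
    grammars and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
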
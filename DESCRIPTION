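Package: ppphylo
Title: Constrained Persistent Perfect Phylogeny for Binary Character Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether a binary species-by-character matrix admits a
    persistent perfect phylogeny (each character gained at most once and lost
    at most once) under optional forbidden-persistence constraints, and builds
    and verifies such a tree when one exists. Implements the red-black graph
    character-realization machinery, a polynomial-time solver for matrices
    with edgeless conflict graphs, a fixed-parameter depth-first search over
    c-reductions with red-sigma pruning, a brute-force completion-enumeration
    oracle for validation, a coalescent-style synthetic instance generator
    with back-mutation injection, and annotated Newick input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
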
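# ppphylo

Constrained persistent perfect phylogeny for binary character matrices.

## The problem

A binary matrix *M* (species × characters) is explained by a **directed
perfect phylogeny** when a rooted tree with an all-zero root exists in
which every character mutates 0 → 1 on exactly one edge (the
infinite-sites assumption). Haplotype data, protein-domain repertoires
and tumor marker profiles routinely break that assumption through back
mutations: a character is acquired and later shed. The **persistent
perfect phylogeny** (p-pp) model admits exactly this relaxation — per
character at most one gain edge (*c*⁺) and at most one loss edge (*c*⁻),
the loss below the gain on the same root path. The **constrained**
problem (CPPP) additionally takes pairs (*c*, *s*) with *M*[*s*, *c*] = 0
that forbid *c* from ever appearing on the root path of species *s*.

`ppphylo` decides CPPP, constructs and verifies the tree, and ships the
machinery around it: the extended-matrix encoding (each character split
into a conjugate column pair (*c*⁺, *c*⁻) with (?, ?) marking undecided
persistence), the red-black graph and its character-realization
operator, a polynomial-time greedy solver for matrices whose conflict
graph is edgeless, a fixed-parameter depth-first search over
c-reductions for the general case, a brute-force enumeration oracle used
as ground truth, a coalescent-style instance simulator with
back-mutation injection, annotated Newick output, a mapping to the
three-state general character compatibility problem, and a command-line
interface.

## Worked example

The smallest interesting instance: three species with rows (1,0), (1,1),
(0,1). Its two characters are pairwise compatible, yet no perfect
phylogeny exists — `c1` must be gained, then lost below `c2`'s gain.

```r
library(ppphylo)
M <- cppp_matrix(rbind(s1 = c(1, 0), s2 = c(1, 1), s3 = c(0, 1)))
colnames(M) <- c("c1", "c2")
fit <- cppp(M)
fit
#> Constrained persistent perfect phylogeny
#>   instance: 3 species x 2 characters, 0 constraint(s)
#>   decision: solution
#>   c-reduction: c1+ c2+ c1-
#>   nodes expanded: 1, red-sigma prunes: 0
fit$tree
#> Persistent perfect phylogeny: 4 nodes, 3 species, 2 characters
#>   node 1 (root) parent=0 state=00
#>   node 2 parent=1 state=10 [+c1] {s1}
#>   node 3 parent=2 state=11 [+c2] {s2}
#>   node 4 parent=3 state=01 [-c1] {s3}
```

The c-reduction `c1+ c2+ c1-` is the depth-first edge-label sequence of
the tree: a chain gaining `c1`, then `c2`, then losing `c1`, so `c1` is
*persistent* for `s3`. The completed extended matrix records that as the
(1, 1) pair in row `s3`:

```r
fit$completed$cells
#>    c1+ c1- c2+ c2-
#> s1   1   0   0   0
#> s2   1   0   1   0
#> s3   1   1   1   0
write_cppp_newick(fit$tree)
#> [1] "(((s3[&losses=c1])s2[&gains=c2])s1[&gains=c1]);"
```

Forbidding that persistence makes the instance infeasible:

```r
cppp(M, cppp_constraints(character = "c1", species = "s3"))$status
#> [1] "no-solution"
```

`verify_ppp(fit$tree, M)` re-checks any tree against the definition
(all-zero root, labeled edges, one gain/one loss per character with the
loss below the gain, rows matching node states, constraints respected),
and `oracle_decide(M)` gives the brute-force decision for small
instances. A shell entry point with `solve`, `verify`, `simulate`,
`oracle` and `conflicts` subcommands is installed at `exec/cppp`
(see `?cppp_cli`).

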
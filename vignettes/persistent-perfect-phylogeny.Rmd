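---
title: "Constrained persistent perfect phylogeny: model, algorithms and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained persistent perfect phylogeny: model, algorithms and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppphylo)
```

## The model

A binary character matrix $M$ over $n$ species and $m$ characters records
whether species $s$ possesses character $c$ ($M[s,c]=1$). The classical
*directed perfect phylogeny* explains $M$ by a rooted tree with an
all-zero root in which each character mutates $0 \to 1$ on exactly one
edge — the infinite-sites assumption. Real data (back mutations in
haplotypes, protein domains acquired and later shed, tumor marker
reversions) frequently violate it in a specific, mild way: a character is
gained once and later lost once. The *persistent perfect phylogeny*
(p-pp) admits exactly this: per character, at most one gain edge
(labeled $c^+$) and at most one loss edge (labeled $c^-$), the loss on
the same root path strictly below the gain. A character whose root path
to species $s$ crosses both edges is *persistent for* $s$.

The *constrained* problem (CPPP) additionally takes a set $F$ of pairs
$(c, s)$ with $M[s,c] = 0$, each forbidding any $c^+$ edge on the root
path of $s$ — i.e. $c$ may never appear in the ancestry of $s$, not even
transiently. Solving CPPP means deciding whether a tree satisfying all
of the above exists and constructing one when it does.

### The extended matrix and its completions

Every character $c$ is split into a conjugate column pair $(c^+, c^-)$:

* $M[s,c]=1 \mapsto (1,0)$ — gained, not lost above $s$;
* $M[s,c]=0$, $(c,s) \in F \mapsto (0,0)$ — frozen by the constraint;
* $M[s,c]=0$ otherwise $\mapsto (?,?)$ — undecided: either $(0,0)$
  (never gained) or $(1,1)$ (gained then lost, persistent for $s$).

The instance is solvable iff some completion of the `?` pairs yields a
$n \times 2m$ matrix admitting a directed perfect phylogeny, which holds
iff no two columns exhibit all three configurations $(0,1)$, $(1,0)$,
$(1,1)$ (equivalently, the columns form a laminar family of species
sets). `extend_matrix()`, `complete_pair()` and `admits_directed_pp()`
implement this layer, and the brute-force `oracle_decide()` is nothing
but this equivalence made executable by exhaustive enumeration — it is
the package's ground truth and deliberately shares no code with the
solvers.

### The red-black graph and c-reductions

The solvers operate on the bipartite *red-black graph*: species and
characters are vertices, a **black** edge $(s,c)$ marks an unresolved
possession ($c$ not yet realized, pair $(1,0)$), a **red** edge marks a
persistence completion ($c$ realized, pair $(1,1)$). *Realizing* a gain
$c^+$ of an inactive character completes the pairs of all species
outside $c$'s connected component as $(0,0)$, turns the in-component
non-neighbors into red neighbors ($(1,1)$), drops $c$'s black edges and
marks $c$ *active*; realizing a loss $c^-$ requires the active $c$ to be
red-adjacent to its entire component, deletes those red edges and marks
$c$ *free*. A gain that would force $(1,1)$ onto a constrained cell is
*impossible* — the constrained analogue of an unrealizable character. An
ordered sequence of signed characters whose realization empties the
graph is a *successful c-reduction*; it determines a completion and
hence a tree.

In this package the graph is not a separate mutable structure: black and
red edges are derived from the cells and the status vector (`rb_state()`,
`red_black_graph()`), which makes the graph invariants true by
construction and backtracking a matter of keeping the previous state.

### The conflict graph and the polynomial case

Two characters *conflict* when their columns induce all four
configurations. If the conflict graph (`conflict_graph()`) is edgeless,
`solve_edgeless()` finds a successful c-reduction greedily: per connected
component, realize the realizable maximal characters of the containment
order (`character_poset()`), then free every active character covering
its component, and iterate; if some component's maximal characters are
all unrealizable, there is no solution from this state. Without
constraints this always succeeds. The structural facts behind the greedy
choice — maximal characters are pairwise adjacent in the adjacency
graph, and realizing them leaves red edges and active characters in at
most two components — are enforced as property tests rather than taken
on faith.

### The general search

`cppp()` explores the tree of c-reduction prefixes depth first. At each
node it (i) succeeds if the graph is edgeless, (ii) abandons the branch
if a red-sigma certificate is present, (iii) jumps to the greedy solver
when the residual conflict graph has become edgeless, and otherwise
(iv) expands the feasible moves. Since every signed character occurs at
most once in a prefix, the tree is finite and the search is
fixed-parameter in $m$; the first solution wins, as no optimality
criterion distinguishes solutions.

## Design decisions

**Move ordering.** No branching order is prescribed by the problem, so a
deterministic heuristic is used: losses before gains (freeing only
shrinks the graph), then gains with poset-maximal characters first
(mirroring the greedy solver's logic), then by decreasing residual
column count, then by name. Determinism makes traces reproducible.

**Greedy solver from interior states.** When the search jumps to
`solve_edgeless()` at a node that already has active characters, a
greedy failure is treated as "keep expanding", not "prune": the greedy
procedure's completeness argument starts from red-edge-free states, and
its behavior from arbitrary interior states is not established. This
choice preserves search completeness at the cost of some redundant work.

**Maximality scope.** "Maximal elements in the same connected component"
is read as maximal *within* the component (among characters still
inactive), computed against the containment order of the residual matrix
at entry. Equal columns are a single tie class, realized consecutively
(decreasing 1-count, ties by the class's first name).

**The red-sigma certificate is sound but, here, vacuous as a prune.** A
red-sigma — a red path $s_1 - a - s_2 - b - s_3$ whose completed columns
show $M_e[s_3,a^+] = M_e[s_1,b^+] = 0$ — certifies that a partial
completion admits no directed perfect phylogeny; `detect_red_sigma()`
implements it and the suite confirms against the oracle that states
containing one are unsatisfiable. However, under the global realization
semantics used here a red-sigma is unreachable along feasible move
sequences: red edges are attached to a character only at its own gain,
covering exactly the non-black part of its component, and an active
character's red star keeps those species connected — so a later gain
either engulfs the whole star (completing the would-be-zero cell to 1)
or touches none of it. Exhaustive exploration of all feasible sequences
on small instances found no reachable sigma state. The check is retained
(it is cheap and guards any future change of realization semantics), but
branch pruning in practice happens through move infeasibility, and the
"pruned branch" audit in the acceptance suite consequently finds no
events to count.

**Reason codes.** Impossibility reasons are `free-character`,
`active-not-covering` (covers both a non-covering active loss and a loss
requested on an inactive character — the freeing condition is simply not
met), `constraint-violation` (including the defensive re-check that an
existing red edge never sits on a constrained cell), and `wrong-state`
for a gain on a non-inactive character, which the three canonical
reasons cannot express.

**Duplicates.** Duplicate rows and columns are never removed silently;
`dedup_matrix()` (and the CLI `--dedup` flag) does it explicitly and
returns merge maps. The size bound $n/2 \le m \le 2n$ for explainable
matrices presumes duplicate-free instances, but real inputs legitimately
contain duplicates — they are where back mutations live.

**Tree construction.** Trees are built from the completed matrix through
the classical all-zero-root construction on the $2m$ columns (sorted by
decreasing 1-count; ties gain-before-loss, then name; identical columns
share an edge), then collapsed to length-$m$ node states. This route is
justified by the completion equivalence and gives a canonical tree;
replaying the label sequence directly would require a reconstruction
procedure that is asserted but not specified. Nodes exist only at
mutation points and identical rows share a node (the definition speaks
of rows labeling nodes, not leaves). All-zero columns never label an
edge; their pairs are completed $(0,0)$ when a successful reduction
finishes, which is their canonical completion.

**Memoization.** `cppp(memoize = TRUE)` caches canonical states (status
vector plus completion fingerprint) and skips re-exploration; it is off
by default because it trades memory for time and the default should be
the plain, easily-audited search. The scaled protocol harness switches
it on.

## The synthetic generator

`sim_pp_matrix()` emulates coalescent-style infinite-sites data: a
random rooted tree grown by uniform sequential attachment until $n$
leaves exist, $m$ mutations dropped uniformly on edges (with
replacement, so duplicated columns occur naturally), rows read off the
leaves. Columns are subtree leaf-sets, so the pre-perturbation matrix
always admits a perfect phylogeny and has an edgeless conflict graph. A
`duplicate_row_rate` fraction of rows (default 0.3 in
`sim_cppp_instance()`, 0.4 in the scaled protocol below, where
perturbation pressure is the point) is overwritten with copies of other
rows; `inject_back_mutations()` then flips at most one uniformly chosen
entry in each duplicated row — the minimal infinite-sites violation the
persistent model is designed to absorb. `sim_constraints()` samples
forbidden-persistence pairs uniformly from the zero cells.

What the generator does *not* emulate: recombination, recurrent (as
opposed to back) mutation, mutation-rate heterogeneity, and genuine
coalescent branch-length distributions. Passing tests therefore show
correctness of the algorithms on matrices with the right combinatorial
structure (perfect-phylogeny backbone plus sparse single-state
perturbations), not robustness to arbitrarily structured real data.

## Problem sizes and numerical choices

The suite and `scripts/acceptance.R` work at desk scale, chosen so the
whole suite runs in a few minutes: exhaustive checks on all 512 binary
$3\times3$ matrices and all 4096 $3\times4$ column layouts; several
hundred random instances with $n, m \le 5$ and up to two constraints
(where the enumeration oracle is exact); 200 edgeless-conflict instances
with $4 \le n \le 10$; and a scaled protocol of 20 instances per
$(n, m) \in \{10\} \times \{5, 7, 10\}$ with a 3000-node search budget.
There is no floating point anywhere — all computations are integral —
so no tolerances are involved; determinism is controlled entirely by
seeds and the fixed tie-breaking rules above.

## Known limitations

* The depth-first search is exponential in $m$ in the worst case (the
  problem's complexity is open); hard conflicted instances at
  $m \gtrsim 10$ can exhaust realistic node budgets, and the solver then
  reports `budget-exceeded` rather than a decision.
* The greedy edgeless solver is only known complete from fresh states;
  from interior search states its failures trigger re-expansion, which
  can duplicate work.
* The oracle is exponential in the number of undecided pairs by design
  and refuses instances beyond its limit; it validates, it does not
  solve.
* Multi-state characters and the general set-valued compatibility
  problem are out of scope; `export_gcc()` only writes the specific
  three-state image of a CPPP instance.
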
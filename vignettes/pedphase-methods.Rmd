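---
title: "Minimum-recombination pedigree phasing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-recombination pedigree phasing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedphase)
```

## The model and its assumptions

A pedigree is a set of members connected by parent-offspring trios; each
member carries two haplotypes over `m` biallelic SNP sites, observed only as
a genotype vector over `{0, 1, 2}` (0/1 = homozygous, 2 = heterozygous).
Under Mendelian inheritance a child receives one complete haplotype from
each parent; a crossover during meiosis instead transmits a mosaic of the
parent's two haplotypes, and each source switch between adjacent informative
sites is one recombination event. `solve_rhc()` finds a haplotype assignment
for every member, consistent with every genotype, that minimizes the total
number of events — the parsimony criterion appropriate for short windows of
tightly linked markers, where true crossovers are rare.

Assumptions inherited from this model: no missing genotypes and no
genotyping errors (violations are rejected up front, not imputed); biallelic
sites only; autosomal inheritance (the sex column is parsed and preserved
but never used); every member has either both parents in the pedigree or
neither. General pedigree topologies, including loops created by
inter-marriage, are supported; the parent relation must merely be acyclic.

Recombination events are counted per transmission and localized between the
two nearest *source-constrained* sites flanking the switch: a breakpoint
between sites where the parent is homozygous is undetectable in principle,
so the reported count is the minimal one, which is the only well-defined
choice. `count_recombinations()` implements this scoring independently of
the solver and doubles as the internal verifier.

## From pedigree to signed graph

Phase is captured pairwise. For every pair of *consecutive heterozygous*
sites `(i, j)` of member `u` there is a vertex for the unknown flip of `u`'s
haplotypes between `i` and `j`: *green* when `h1` carries equal alleles at
both sites, *red* when it flips. Consecutive homozygous pairs give resolved
(red/green) vertices directly from the genotype. The flip of any wider
heterozygous pair is the XOR along the chain of consecutive pairs, so
non-consecutive patterns are represented, when a constraint needs them, by a
*supplementary* vertex tied to the chain by a parity-constraint set: a
vertex set in which the number of red vertices (plus a fixed offset) must be
even in any valid phasing.

The key structural fact used by the construction: in a transmission from
parent `p` to child `c`, the minimal number of source switches equals the
number of consecutive-heterozygous pairs `(a, b)` of `p` whose *delivered*
flip (the pattern of the transmitted alleles at `a` and `b`) differs from
`p`'s own phase flip at `(a, b)`. The delivered allele at a site is:

* fixed by the genotype when the child is homozygous there;
* fixed when the child is heterozygous but either parent is homozygous
  there (the other parent must supply the complementary allele);
* otherwise — child and both parents heterozygous — a genuinely free binary
  choice shared by the two parents (one delivers an allele, the other its
  complement).

Free deliveries are materialized as grey *delivery vertices*; fully pinned
transmitted patterns become resolved *constant vertices*. Every per-pair
cost term is then a single signed edge: positive (+1) when the two endpoint
variables must agree unless one recombination occurs, negative (−1) when
they must disagree. The classical special cases fall out naturally: when
child and both parents are heterozygous at both sites of a pair, each
parent's vertex is linked positively to the child's segment vertex; when the
child is heterozygous at exactly one site, the two parents are coupled
through the shared delivery vertex by a +/− edge pair, which behaves exactly
like a direct negative parent-parent edge. Hard, cost-free consequences of
pinned deliveries are applied outright: a child chain vertex whose two
endpoint deliveries are both pinned is colored (pinned) during construction,
and chain vertices with one or two free endpoint deliveries are tied to the
delivery vertices by 2- or 3-element parity sets with the pinned values as
offsets. A grey vertex that ends up with no edge and no parity membership is
a free phase variable — a recombination across its interval is undetectable
— and is pruned (logged).

The resulting graph has `O(n·m)` vertices and edges for `n` members (well
inside the `3·n·m²` envelope asserted by the tests), is built
deterministically in file order, and construction is idempotent.

For a red/green coloring of the vertices, the *line index* — positive edges
joining different colors plus negative edges joining equal colors — counts
the recombination events, and the pedigree admits a configuration with at
most `k` events exactly when some parity-feasible coloring extending the
resolved colors has line index at most `k`. This correspondence is not taken
on faith: the test suite checks it, pedigree by pedigree, against an
exhaustive phasing oracle on a simulated corpus.

## Reduction to bipartization by edge removal

Three mechanical transformations turn line-index minimization into graph
bipartization by edge removal (GBER):

1. every positive edge `(u, v)` becomes two negative edges `(u, y)`,
   `(y, v)` through a fresh intermediate vertex `y` that belongs to no
   member and no parity set — the line index is unchanged, since `y` can
   always be placed on the cheaper side;
2. negative edges joining two resolved vertices contribute a
   partition-independent constant (`baseline_cost`, with provenance kept
   for event reporting) and are removed — merging would otherwise create
   self-loops;
3. all red vertices are merged into one anchor, all green into another, the
   two anchors are joined by `budget + 1` parallel negative edges (making
   any in-budget solution separate them, so "the red side" is always
   well-defined), and every weight is negated.

The question is now: delete at most `budget = k − baseline_cost` edges so
that the remaining multigraph is 2-colorable, with every parity set even.

## The solver

`solve_gber()` uses iterative compression. Edges are inserted in a fixed
deterministic order (anchor gadget edges first, then provenance order); a
minimum-size parity-feasible removal set `X` is maintained. When the next
edge breaks `X`, the candidate `X' = X ∪ {e}` is compressed: each `X'` edge
is subdivided into three (so a smaller disjoint solution exists iff any
smaller solution does — the subdivision preserves all cycle parities and
does not touch parity sets), the `2^|X|` valid partitions of the subdivision
endpoints are enumerated (one orientation fixed by symmetry), and for each
partition an Edmonds–Karp maximum flow bounded by `|X|` yields the minimum
cut between the sides. Undirected unit edges become mutually-reverse arc
pairs of capacity one; multiple sources/sinks are absorbed by
super-terminals with infinite capacity.

Rather than enumerating the possibly `2^n` minimum cuts, the residual graph
is condensed by strongly connected components (via igraph) into a DAG whose
successor-closed component sets containing the source component — and not
the sink's — are in bijection with the minimum cuts. A backtracking search
over the free components, in reverse topological order with the closure
constraint propagated, visits candidate cuts until a parity-feasible one is
found.

Parity feasibility of a candidate removal set is decided exactly and
cheaply: 2-color each connected component of the remaining graph (BFS),
orient the components containing anchors, and treat the remaining
per-component flips together with the colors of constraint-free vertices as
unknowns of a GF(2) linear system with one equation per parity set; Gaussian
elimination either refutes or produces a witness coloring.

Two search modes exist because minimum cuts are not the whole story under
parity constraints: a parity-feasible bipartization set of size `k'` always
induces *a* cut for some valid partition, but not necessarily a *minimum*
one. `paper_faithful` (the default) searches minimum cuts only — it can
therefore overshoot the optimum on rare instances, though never undershoot
it. `exhaustive_fallback` additionally brute-forces removal subsets of size
`k'` (guarded by an instance-size cap) whenever the mincut search fails, and
the diagnostics record whether the fallback actually fired. The test suite
compares both modes against a parity-restricted exhaustive oracle and
reports every discrepancy it finds; the headline corpus comparison runs in
fallback mode so that exactness is unconditional.

`solve_rhc()` searches `k = 0, 1, ..., k_max` upward, rebuilding the
transformed instance per `k` (the anchor gadget depends on the budget), so
the first feasible `k` is the true minimum. Decoded phases are re-scored
with `count_recombinations()` before returning; the result carries both the
re-scored events (single parent, minimal interval) and the
provenance-localized graph events.

## Tunable parameters

* `k_max` (default 10): upper bound on the event count searched; running
  time grows like `2^k`, so the CLI warns beyond 12.
* `mode`: `paper_faithful` or `exhaustive_fallback`, as above.
* `oracle_limits()`: enumeration guards for the brute-force references
  (default: ≤ 8 members, ≤ 8 sites, ≤ 18 free phase bits, ≤ 20 vertices) —
  deliberately tight, since the oracles exist for validation, not analysis.
* Simulation (`simulation_spec()`): founder couples, children per couple,
  generations, `m`, planted breakpoint count, founder allele frequency
  (default 0.5, which maximizes heterozygosity — the hard regime for
  phasing), seed, and `allow_loops` (marriages across sibships, never
  lineal, so multiple inheritance paths arise without incest between
  ancestor and descendant).

## What the simulator does and does not emulate

`simulate_pedigree()` draws founder haplotypes i.i.d. per site, transmits
haplotypes down the pedigree with *exactly* the requested number of planted
breakpoints placed uniformly without replacement over (transmission,
interval) slots, and derives genotypes. It emulates the inputs the method is
designed for: small dense marker windows, error-free genotypes, known
pedigree structure. It does not emulate linkage disequilibrium between
founder haplotypes, recombination hot-spots or interference, genotyping
error, or missingness — so green tests certify algorithmic correctness on
the stated model, not robustness to real-data artifacts. Because planted
breakpoints may fall between uninformative sites, the planted configuration
is only a witness: the inferred minimum can be smaller than the planted
count, and tests assert `≤`, never `=`.

The validation corpus mirrors the intended operating range: families of one
or two couples across up to three generations (n ≤ 6), m between 2 and 4,
zero to two planted events, two hundred replicates per run; the graph size
bounds are additionally checked on one thousand pedigrees with n ≤ 10 and
m ≤ 6. Looped pedigrees are exercised separately in the property tests.

## Numerical and degenerate-input choices

* All tie-breaks are deterministic: members in file order, sites ascending,
  edges in provenance order, partitions in binary-counter order; identical
  inputs yield byte-identical outputs.
* `h1` of every member carries allele 0 at the member's first heterozygous
  site; swapping `h1`/`h2` of any member is a documented symmetry, and
  `count_recombinations()` is invariant under it.
* Members with at most one heterozygous site, single-member pedigrees and
  `m = 1` all degenerate gracefully (empty graphs, `k = 0`).
* Negative-edge events are attributed through the edge's provenance to the
  parent whose transmission the edge scores; re-scored events always name a
  single parent and the minimal flanking interval.
* Pin conflicts during construction (two hard forcings disagreeing) cannot
  arise for Mendelian-consistent input; they are logged rather than fatal,
  and the Mendelian check runs before solving in any case.
* A parity set whose variables are all resolved and whose offset is odd
  makes the instance infeasible at every budget; the solver reports
  infeasibility rather than erroring.

## Known limitations

* Running time is exponential in `k` (by design) and the oracles in the
  problem size (by construction); neither is suitable for genome-scale
  phasing or large `k`.
* Exactly one optimal configuration is returned; co-optimal configurations
  are not enumerated, and no posterior uncertainty is attached.
* Multi-allelic markers, missing data, genotyping error, and X-linked
  inheritance are out of scope.
* The `paper_faithful` search can exceed the optimum on instances where no
  minimum cut is parity-feasible; use `exhaustive_fallback` when exactness
  matters more than strict adherence to the mincut-only strategy.

## A compact session

```{r example}
ped <- pedigree(id = c("f", "v", "c1", "c2"),
                father = c(NA, NA, "f", "f"),
                mother = c(NA, NA, "v", "v"),
                geno = rbind(c(2, 2), c(0, 0), c(2, 0), c(2, 2)))
res <- solve_rhc(ped, k_max = 3)
res$k
res$events
brute_force_min_recombination(ped)$k
```
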
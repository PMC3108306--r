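# pedphase

Minimum-recombination haplotype phasing on general pedigrees.

## The problem

Diploid genomes carry two haplotypes per chromosome, but routine genotyping
only reports the unordered allele pair at each SNP site (coded `0` =
homozygous reference, `1` = homozygous alternate, `2` = heterozygous). For
family data the phase of every member can be inferred computationally: under
Mendelian inheritance each child receives one complete haplotype from each
parent, except where meiotic crossovers produced a recombinant. The
*minimum-recombination haplotype configuration* (MRHC) problem asks for
haplotypes `h1_u, h2_u` of every member `u`, consistent with all genotypes,
that minimize the total number of recombination events across the pedigree —
the standard parsimony criterion for tightly linked markers. The problem is
NP-hard even for small site counts, but it is fixed-parameter tractable when
the number of sites `m` and the number of events `k` are small — the regime
of this package, aimed at genetic-disease studies of short marker windows on
arbitrary (including looped) pedigrees.

`pedphase` is intended for methodologists and analysts who need *exact*
minimum-recombination phasings with event localization on desk-scale
pedigrees, plus the machinery around that: simulation with planted
crossovers, Mendelian checking, brute-force oracles, and solver diagnostics.

## The method

1. **Pedigree graph.** Each member contributes one vertex per pair of
   consecutive heterozygous sites (its unknown phase "flip" pattern: *green*
   = same allele on h1 at both sites, *red* = flipped) and one resolved
   vertex per consecutive homozygous pair. For every parent-offspring trio,
   the number of crossovers in a transmission decomposes exactly over the
   parent's consecutive-heterozygous pairs; each pair contributes one signed
   edge (weight +1 = endpoints must match, −1 = must differ) against either
   the child's segment vertex, a free *delivery* vertex (the transmitted
   allele at a site where all three members are heterozygous), or a resolved
   constant. Violating an edge costs exactly one recombination event.
   Zero-cost hard relations become pinned colors or *parity-constraint
   sets*: vertex sets in which the number of red vertices must be even (up
   to a fixed offset).
2. **Line index.** A red/green 2-coloring of the vertices has *line index*
   = (positive edges joining different colors) + (negative edges joining
   equal colors); the pedigree admits a configuration with at most `k`
   events iff the graph has a parity-feasible coloring with line index ≤ k.
3. **Bipartization by edge removal.** Positive edges are split into two
   negative edges through fresh intermediate vertices (this preserves the
   line index); constant edges are folded out; all red vertices are merged
   into one anchor and all green vertices into another, joined by `k+1`
   parallel edges; negating every weight turns the question into *graph
   bipartization by edge removal* (GBER): delete ≤ k edges to make the
   multigraph bipartite, subject to the parity sets.
4. **Iterative compression.** Edges are inserted one at a time while a
   minimum parity-feasible removal set `X` is maintained. When `X` stops
   working it is compressed: all `2^|X|` valid partitions of the endpoints
   of `X ∪ {e}` are enumerated, a bounded Edmonds–Karp maximum flow finds
   the minimum cut per partition, and the Picard–Queyranne closure structure
   (strongly-connected-component condensation of the residual graph) is
   searched for a parity-feasible minimum cut without enumerating the
   possibly exponential number of mincuts one by one. Total running time is
   exponential only in `k`.
5. **Decoding.** The side of the red anchor defines the red class; walking
   each member's chain of heterozygous-pair vertices reconstructs `h1`/`h2`,
   and every violated edge maps back through provenance to a localized
   recombination event (child, parent, flanking site interval).

The mincut-only parity search is the published strategy; `pedphase` also
ships an `exhaustive_fallback` mode because rare instances exist where no
minimum cut is parity-feasible yet a slightly larger cut is optimal — the
solver reports which mode produced the answer. See the methods vignette
(`vignettes/pedphase-methods.Rmd`) for the full model, design decisions and
limitations.

## Worked example

A nuclear family genotyped at two SNP sites: father heterozygous at both,
mother homozygous reference, one child `20` and one child `22`:

```
F1  f   0  0  1  22
F1  v   0  0  2  00
F1  c1  f  v  1  20
F1  c2  f  v  2  22
```

```sh
$ Rscript inst/scripts/pedphase phase --input fam.ped --k-max 3
pedigree: 4 members, 2 sites, 2 trios
graph: 5 vertices, 2 edges, 0 parity sets
k = 0: infeasible (phi tried 1, mode paper_faithful)
k = 1: feasible (phi tried 1, mode paper_faithful)
minimum recombination events: k = 1
f	01	10
v	00	00
c1	00	10
c2	00	11
#events	k=1
c2	f	(1,2)
```

Whatever phase the father takes, only one child can inherit an intact
paternal haplotype: the minimum is exactly one recombination event, here
localized to the father's transmission to `c2` between sites 1 and 2. Each
member's row gives its two inferred haplotypes (`h1`, `h2`); `h1` carries
allele 0 at the member's first heterozygous site (the two haplotypes of a
member are interchangeable). The same computation in R:

```r
library(pedphase)
ped <- parse_pedigree("fam.ped", dialect = "compact")
res <- solve_rhc(ped, k_max = 3)
res$k        # 1
res$events   # child c2, parent f, interval (1,2)
```

Other subcommands: `simulate` (synthetic pedigrees with planted, seeded
crossovers plus ground truth), `oracle` (exhaustive minimum for small
inputs), `graph-dump` (DOT/JSON export of the constructed graph).

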
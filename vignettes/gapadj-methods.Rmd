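---
title: "Reconstructing ancestral gene orders from gapped adjacencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral gene orders from gapped adjacencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapadj)
```

# The problem

Given the gene orders of a set of extant genomes, a species tree whose
leaves they label, and an internal node $\nu$ of interest, the *small
phylogeny* problem asks for the gene order of the ancestral genome at
$\nu$. `gapadj` takes the synteny-based route: instead of minimising a
rearrangement distance, it scores observable conservation of *gapped
adjacencies* across the tree and chains the best-supported relations
into Contiguous Ancestral Regions (CARs). The output is a set of CARs —
runs of signed genes whose internal junctions all clear a support
threshold — rather than a genome forced to be fully assembled.

The evolutionary model permits arbitrary rearrangements (only their
traces, broken adjacencies, are consulted), gene losses and gains, and
whole-genome duplication (WGD) as the sole source of multi-copy genes.
WGD events appear as single-child nodes of the species tree whose label
is the genome immediately *preceding* the doubling, so the target node
$\nu$ — a speciation preceding all WGDs, or a first WGD node — carries
exactly one copy of each gene.

# Genomes, markers and gapped adjacencies

A genome is a set of chromosomes; a chromosome is a sequence of signed
genes. Linear chromosomes are circularised by appending an artificial
telomeric gene $O$ (always read positively), so both topologies are
handled uniformly; $mult(O, G)$ equals the number of linear
chromosomes. Each signed gene expands to an ordered pair of unsigned
markers, $+g \mapsto (g^t, g^h)$ and $-g \mapsto (g^h, g^t)$.

A signed gene $b$ is a **left $\alpha$-adjacency** of gene $a$ when the
number of markers strictly between $b$'s relevant extremity and $a^t$
is smaller than $\alpha$; right adjacencies are symmetric. $\alpha = 1$
is direct adjacency; growing $\alpha$ admits pairs separated by up to
$\lfloor(\alpha-1)/2\rfloor$ intervening genes. `alpha_adjacencies()`
returns the multiset $LA(g, \alpha, G)$ (or $RA$), aggregating over
occurrences of both $+g$ and $-g$ (reverse occurrences are read
reversed with signs flipped). Three conventions matter:

* **Strict gap exclusion** (default on): a contribution whose gap
  window contains a copy of the focal or the contributed gene is
  suppressed, following the substring characterisation in which the gap
  sequence ranges over $\pm\Sigma - \{a, b\}$. The pure marker-gap
  variant is available by flag; the two differ only when tandem copies
  sit inside a window.
* **$O$ is orientation-free.** Because $O$ never carries a sign, its
  left and right sides swap with the (arbitrary) writing direction of a
  chromosome. Wherever $O$'s two sides must be compared across genomes
  — conservation counts and conservation scoring — its multisets are
  folded over orientation ($LA(O) \uplus -RA(O)$), one element per
  telomeric junction. Without this folding the invariant that every
  conserved junction is counted exactly twice fails.
* Adjacency multisets are intrinsic: rewriting a chromosome in the
  opposite direction changes nothing, and negating all signs without
  reversing swaps left with right. (These, rather than a naive
  "reversal negates the multisets" rule, are the identities the test
  suite asserts; the naive rule is false once occurrences of both signs
  are aggregated.)

Conservation between two genomes is counted per gene as
$adjCons(g,\alpha,G_u,G_v) = |LA_u \cap LA_v| + |RA_u \cap RA_v|$
(multiset intersections), summed over shared genes, branches, and —
with a labeled tree — the whole phylogeny (`adj_cons_tree()`). Each
conserved junction contributes twice, once from each incident gene.

# Ancestral gene content

`assign_gene_content()` fills every node's gene set and multiplicities
in two bottom-up passes. First, each WGD node receives every gene whose
maximum multiplicity over the node's *direct descendants* (nearest
leaves/WGD nodes below with no intervening WGD) is at least 2, at
pre-duplication multiplicity $\lceil m/2 \rceil$ — the ceiling so that
an odd descendant count is still coverable by the doubled ancestor.
Second, every gene spans the paths from the LCA of its carriers (leaves
or WGD nodes) to its carrying leaves, with unset multiplicities the
maximum over children. The construction never lets multiplicity grow
down a branch (beyond 0 to 1 gains) except across a WGD, where it may
at most double. `insert_wgd_nodes()` can place WGD nodes automatically
from leaf multiplicities (each leaf needs
$\lceil \log_2 \max_g mult(g) \rceil$ events on its root path, shared
events placed as high as possible); explicit `WGD` annotations in the
Newick input override it, and conflicting requirements raise an error
rather than guessing.

# Scoring candidate adjacencies

For the assembly we need, for each gene $g$ at a CAR extremity and each
candidate signed partner $h$, the **adjacency conservation score**: the
maximum number of times the gapped adjacency $(g, h)$ can be conserved
along branches of the tree, over all ancestral labelings with
$LA(g, \alpha, G(\nu)) = \{h\}$. Because only the one adjacency is
counted, the maximisation decouples: an internal carrier node can
always include $h$ among its $mult(g, u)$ adjacency slots at no cost,
while a leaf contributes the number of copies of $h$ in its observed
window (capped at the gene's multiplicity). The score is therefore the
closed form

$$L(g, h) = \sum_{(u,v)} \min\!\big( (1 + [u\ \mathrm{WGD}]) \cdot a_u,\; a_v \big),$$

over carrier branches, with $a_u = mult(g, u)$ at internal nodes and
the capped observed count at leaves; a WGD doubles the parent side
because the doubling duplicates every adjacency (`wgd_double_match`
turns this off). A wildcard partner — any value observed at no leaf —
still collects the internal-internal terms (an adjacency may have
existed ancestrally and died before every leaf), which is exactly the
floor that the cut threshold must clear.

The package also implements the pooled variant in which *all* of
$g$'s side-adjacencies count, as an inside–outside dynamic program over
candidate multisets of size $mult(g, u)$ drawn from the observed
alphabet plus the wildcard (`compute_score_tables()`,
`score_tables_at_node(method = "total")`). A compiled kernel handles
multiplicities up to 2 with closed-form message maximisation; an R
fallback covers higher multiplicities up to a complexity cap (default
4), above which the gene is refused by name. The test suite checks the
DP against exhaustive enumeration of all joint labelings on small
instances. The pooled score is not used for junction weights: its value
carries a tree-shape-dependent baseline (conservation of *other*
adjacencies of $g$, freely arranged deep in the tree), and under a
fixed threshold that baseline swamps the signal exactly on small or
WGD-bearing trees — on the three-leaf WGD fixture the baseline alone
reaches ~0.8 of capacity, so every junction would pass a 0.70 cut and
the ancestor would collapse to a single CAR.

# Assembly: TSP with threshold cutting

`gapadj()` initialises one CAR per gene of $\Sigma_\nu$ and iterates
for $\alpha = 1, \dots, MAX_\alpha$:

1. score the genes at current CAR extremities (only the terminal gene
   of each CAR end is considered; joining deeper "$\alpha$-extremities"
   is deliberately out of scope, matching the published method);
2. build a complete junction graph whose vertices are CAR extremities
   plus a single $O$ vertex. The junction placing signed gene $a$
   before signed gene $b$ weighs
   $$w(a, b) = \frac{L'(a \to b) + L'(b \leftarrow a)}{C(|a|) + C(|b|)},$$
   the two directional scores above, normalised by each gene's
   **conservation capacity** $C(g)$ — the same sum with every leaf
   fully supporting, i.e. the largest score any labeling could reach
   ($C = MaxAdj - 1$, the carrier-subtree branch count, on single-copy
   trees). Weights therefore live in $[0, 1]$ on any tree, including
   across WGD branches, and the threshold reads as the conserved
   fraction of achievable support. The literal per-gene node-count
   normalisation $MaxAdj(g, S)$ of the original description is
   available via `literal_normalization`; it is not the default
   because it exceeds 1 on WGD trees and makes a fixed threshold
   tree-shape dependent.
3. find a heaviest Hamiltonian cycle through the graph (each CAR
   entered at one extremity must be exited at the other). Instances
   with at most 9 CARs are solved exactly by Held–Karp dynamic
   programming over subsets with orientations; larger ones by seeded
   greedy construction plus 2-opt with randomized restarts. Reversing a
   2-opt segment flips the orientations inside it, and junction weights
   are orientation-symmetric, so only the two boundary junctions change
   — the classic symmetric delta. A small improvement floor
   ($10^{-6}$) and a move budget guard against long chains of
   negligible improvements on near-tied instances.
4. cut the $O$ vertex and every junction below $\tau$, concatenate the
   surviving runs (flipping CARs traversed backwards), and record on
   each junction the $\alpha$ that created it.

The CAR count never increases, and the loop stops early at a single
CAR. With the same seed the whole pipeline is bitwise reproducible.

## Parameters

* `tau` (default **0.70**): keep a junction only if its weight — the
  conserved fraction of achievable branch support — reaches 70%.
* `max_alpha` (default **50**): the largest gap bound; no improvement
  is possible beyond the longest chromosome.
* `strict_gap_exclusion` (default on), `wgd_double_match` (default on),
  `literal_normalization` (default off), `mult_cap` (default 4): see
  above.
* `seed`: controls the TSP heuristic's randomized restarts.

# Evaluating an inferred ancestor

`error_rate()` reports the fraction of **inferred adjacencies** — the
junctions chaining consecutive signed genes inside CARs — that are not
gapped adjacencies of the true ancestor, each junction checked at the
gap bound that created it (junctions carry that provenance out of
`gapadj()`; a bare CAR set is checked at `max_alpha`). Telomeric ($O$)
adjacencies are CAR ends, not predictions, and take no part. The
per-junction formulation has a useful calibration: joining $k$ CARs at
random adds about $k - 1$ wrong junctions to the count, so random
completion of a 20-CAR reconstruction of a 200-gene genome raises the
rate by roughly 10 percentage points — the scale against which the
observed sub-4-point increase from widening gaps should be read. A
window-multiset formulation was considered and rejected: there, one
wrong seam poisons every window crossing it, so the statistic grows
quadratically in $\alpha$ and no longer matches that calibration.
`disagreement_fraction()` applies the same junction check of one CAR
set against another at a single fixed gap, and
`summarize_reports()` aggregates replicates.

# The simulator

`simulate_evolution()` generates fully labeled trees so every claim can
be scored against a known truth. The root is an identity genome of
`n_genes` genes in `n_chromosomes` near-equal linear chromosomes. On
each branch, the configured number of gene losses is applied first
(uniformly chosen occurrences; the ordering relative to rearrangements
is immaterial in expectation and fixed for reproducibility), then $r$
rearrangements with $r$ uniform in $[\lceil r_{max}/2 \rceil, r_{max}]$
and kinds drawn Inversion : Translocation : (Fusion+Fission) = 5:4:1
(inapplicable draws are resampled). Inversion segment lengths are
geometric with $p = 0.5$ (mean 2, mostly short inversions); start
positions are uniform over gene positions; translocations exchange
uniform suffixes; fusions flip the joined chromosome with probability
1/2. Crossing a WGD node doubles the genome and applies the configured
burst of post-duplication losses before the branch's own events.

Two fixtures pin the study conditions: the six-leaf topology
`((((A,B),C),(D,E)),F)` with target `SIGMA` (the ancestor of A..E,
whose deepest leaves lie 4 branches from the root), and a three-leaf
tree `(A,(B,C))` with one WGD above the root (target `wgd_R3`, the
pre-duplication node). Default study sizes, chosen to mirror the
simulation study the method was validated on: 200-gene roots, 20
replicates per condition, $r_{max}$ up to 25 (which leaves the deepest
leaves almost fully shuffled), 5 losses per branch and 50
post-duplication losses in the loss-bearing protocols.

What the simulator does **not** emulate — and hence what passing tests
cannot certify about real data: single-gene duplications and
insertions (real inputs must be pre-filtered to WGD-consistent gene
families, as the curated yeast and cereal marker sets are), clustered
or biased breakpoint reuse, rate variation across branches beyond the
configured counts, and any sequence-level effect (orthology is taken
as given).

# Numerical choices and degenerate inputs

* Candidate alphabets are finite by construction: values never observed
  at a leaf cannot beat the wildcard-plus-$O$ options, so collapsing
  them is exact for the pooled DP and trivially exact for the
  adjacency-specific score.
* Ties in the TSP are broken by the seeded randomized restarts;
  junction weights are compared with a $10^{-6}$ floor.
* A single-gene chromosome's only neighbour is $O$; scanning never
  wraps past the focal occurrence itself, so tiny rings are
  well-defined.
* Trees with fewer than 4 nodes cannot clear $\tau = 0.70$ even with
  perfect conservation (a perfect junction weighs $(n-1)/n$ under the
  node-count normalisation and exactly 1 under the capacity default,
  but such trees have at most one informative branch); the method is
  meant for trees with several informative branches.
* The target node must carry exactly one copy of every queried gene;
  anything else is refused as not pre-duplicated.

# Known limitations

* Only the terminal gene of each CAR end is offered for joining, so a
  true neighbour buried inside another CAR by an earlier erroneous
  seam can never be recovered; on heavily rearranged inputs the final
  CAR count therefore plateaus above 1 (typically around 6 for the
  single-chromosome protocol at $r_{max} = 20$) instead of forcing a
  complete assembly. Completion could be bought by letting weights
  inflate with $\alpha$ (the pooled score does exactly that), at the
  price of unconditional merging on small trees; the package prefers
  the calibrated threshold and reports more, cleaner CARs.
* Scores treat each gene and side independently — the published
  relaxation; no joint consistency across genes is enforced.
* Post-WGD loss bursts erase both copies of some genes' contexts; the
  error rate of pre-duplication reconstructions is accordingly several
  times higher than in the loss-free protocols, and genes whose every
  duplicate context is lost drop out of the inferred content.
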
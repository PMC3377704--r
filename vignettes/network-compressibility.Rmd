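---
title: "Power-graph compressibility as a structure statistic for interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-graph compressibility as a structure statistic for interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcompress)
```

## The model

Proteomic regulation is cooperative, modular, and redundant, so a faithful
protein-interaction network is expected to be rich in repeated local
structure: protein complexes appear as **cliques**, shared sub-complexes and
module-to-module wiring as **bicliques**, and hubs as **stars**. A network
that consists of nothing but such motifs can be redrawn much more compactly;
a network of uniformly random interactions cannot. `netcompress` turns this
intuition into a statistic by *losslessly compressing* a network into a
**power graph** and measuring the achieved edge reduction.

A power graph over a graph $G = (V, E)$ is a set of *power nodes* (subsets of
$V$) and *power edges* between them. A power edge between disjoint power
nodes $U$ and $W$ asserts that every node of $U$ interacts with every node of
$W$ (a biclique; a star when $|U| = 1$); a *reflexive* power edge on $U$
asserts that all members of $U$ interact pairwise (a clique). Two conditions
keep the representation readable and well-defined:

* **hierarchy condition** — any two power nodes are disjoint or nested, so
  power nodes form a containment hierarchy;
* **partition condition** — every original edge is abstracted by exactly one
  power edge.

Under these conditions the original network is recovered exactly by expanding
every power edge (`decompress()`), which is what makes the representation a
*compression* rather than a summary. The **compression rate** is

$$\mathrm{CR} = \frac{|E| - |P|}{|E|}$$

where $|P|$ counts all power edges, including the trivial single-edge ones
left over when no larger motif covers an edge. A single isolated edge gives
$\mathrm{CR} = 0$; a complete network collapses to one reflexive power edge.

Dense networks compress partly by chance, so the headline statistic is the
**relative compression rate**: the compression rate minus the mean
compression rate of an ensemble of degree-preserving randomly rewired copies
of the same network,

$$\mathrm{CR}_{rel} = \mathrm{CR} - \overline{\mathrm{CR}}_{random}.$$

Whatever compressibility survives this subtraction cannot be explained by
size, density, or the degree sequence. A complete graph, a perfect matching,
or any network forced by its degree sequence scores exactly zero; planted
cliques and bicliques that rewiring destroys score positive.

## The algorithm

Finding the minimum power graph is a hard combinatorial optimization, so the
package uses the standard two-phase greedy search.

**Phase 1 — candidate power nodes.** Nodes with similar neighborhoods are
nearly exchangeable, so candidates are produced by agglomerative clustering
under the Jaccard similarity of neighborhoods
(`neighborhood_jaccard()`). The similarity of two clusters is the Jaccard
index of their *union* neighborhoods, and merging continues while the best
similarity is positive. Three design choices here were genuinely open:

* *Linkage.* We keep every intermediate merge set as a candidate instead of
  cutting the dendrogram at a similarity threshold: phase 2 is the arbiter
  of which sets are useful, and discarding merge sets can only lose
  coverage. No cut-off parameter therefore exists.
* *Extra candidates.* For every node $v$ we also add $N(v)$ and the set of
  common neighbors of all members of $N(v)$ (a set that always contains
  $v$). These make stars and strongly asymmetric bicliques reachable, which
  pure clustering tends to miss.
* *Singletons* are always candidates, so the search space always contains
  the trivial solution.

**Phase 2 — greedy power-edge search.** Every candidate pair whose complete
biclique is present in the graph (and every candidate that forms a clique of
at least 3 nodes) is a candidate power edge, with gain equal to the number of
edges it abstracts. Candidates are adopted best-gain-first, subject to
(i) *all* of their edges being still uncovered — the partition condition
then holds by construction — and (ii) endpoints being disjoint from or
nested within every already-admitted power node. A candidate must abstract
at least 2 edges (gain 1 is no reduction); leftovers become trivial power
edges and count toward $|P|$.

Because gains are all-or-nothing under rule (i), a single pass over the
candidates in sorted order is exactly equivalent to iterative best-first
selection. Ties are broken deterministically: cliques before bicliques
before stars, then smaller total endpoint size, then lexicographic order of
the sorted member identifiers; vertices are processed in sorted-name order.
The same input therefore always yields the same power graph.

Requiring *all* abstracted edges to be uncovered (not merely some) means
overlapping structures are represented by later, smaller power edges nested
inside the hierarchy — the same convention that renders shared sub-complexes
as nested modules. An alternative would be to split conflicting candidates;
we prefer skipping because it keeps the partition condition structural
rather than repaired after the fact.

`optimal_power_graph()` is an independent brute-force oracle (exhaustive
enumeration of edge-set partitions into valid motifs, guarded to at most 10
edges). The greedy can be suboptimal — on a 5-cycle it needs 4 power edges
where 3 suffice — and the test suite asserts exactly that bounded
relationship, with equality on single-motif graphs.

## The null model and its parameters

The rewiring null model repeatedly replaces two random interactions A–B and
C–D by A–C and B–D, which preserves every node's degree; swaps that would
create a self-loop or duplicate edge are rejected. Tunable parameters:

* `swap_multiple` (default **10**): attempted swaps are
  `swap_multiple * |E|`. The requirement is only "a multiple of the number
  of edges"; 10 makes it very likely that nearly every edge is rewired at
  least once while keeping ensembles cheap.
* `n_random` (default **100** in functions; the headline protocol uses
  1000): the sampling error of the ensemble mean scales as
  $sd/\sqrt{n}$ and is reported alongside the estimate, so smaller
  desk-scale ensembles degrade precision transparently rather than
  correctness. Package tests use 30–100.
* Ensembles are *chains*: member $k+1$ rewires member $k$, with per-step
  seeds derived from the master seed by a counter (`seed + k - 1`), so
  ensembles are reproducible and partitionable.

## Noise models

False positives and false negatives are simulated at the edge level under
two laws: **ER** (uniform over all pairs) and **BA** (degree-biased —
addition samples endpoints proportionally to degree, "the rich get richer";
removal weights an edge by $1/\deg(u) + 1/\deg(v)$, "the poor get poorer").
The exact edge-level removal law is our convention: the verbal description
fixes only that poorly connected proteins lose interactions preferentially,
and the sum of inverse endpoint degrees is the simplest weight with that
marginal behavior. Degrees are frozen at the start of each perturbation for
reproducibility. Perturbation counts are `round(fraction * size)` with
half-up rounding. Node-level noise removes uniformly chosen proteins, or
adds *cloned* proteins: each new node copies the degree of a uniformly
chosen template and is wired to uniformly chosen distinct existing targets
— the degree distribution is minimally perturbed while the new interactions
are completely random. The precise re-wiring procedure for clones was left
open by the verbal description; ours is the simplest that preserves the
clone's degree exactly, and the clone map is exposed for inspection.

## Confidence slicing and assortativity

`slice_matrix()` computes the relative compressibility of every sub-network
between a minimum and maximum confidence score. Both bounds are inclusive
(the convention had to be fixed somewhere; inclusive bounds make the
(min, max) = (lowest, highest) cell exactly the whole network), and the grid
defaults to 20 equal-quantile points of the score distribution, so cells are
balanced in edge count rather than in score span. The baseline subtracted
from every cell is the mean compression rate of rewirings of the *whole*
network, shared across cells, so slices richer in structure than the whole
network stand out; a per-slice baseline is also defensible and available via
`baseline = "per_slice"`.

`assortativity_ratio()` is the fraction of interacting pairs sharing an
annotation among the interacting pairs with complete information about both
partners; pairs with a missing annotation are excluded from numerator and
denominator, and each unordered pair counts once (whether homotypic pairs
should count once or twice was unspecified; once is our convention).
Pair-score categories (e.g. co-expression log-likelihoods) are thresholded
inclusively. `relative_assortativity()` normalizes exactly like the relative
compression rate, holding annotations fixed while rewiring the topology.

## The synthetic generator

`generate_network()` plants node-disjoint (optionally overlapping) cliques,
bicliques, and stars on a fixed node set and adds exactly `noise_edges`
uniform edges avoiding planted pairs. It emulates the *modular* statistical
structure the analyses assume; it does **not** emulate other features of
real interactomes — scale-free degree tails, correlated noise from sticky
proteins, bait/prey asymmetry, or partial motif degradation. Passing tests
on these fixtures therefore demonstrate that the statistics behave as
designed when structure and noise are cleanly separable, not that any
particular real network is well- or ill-measured. `generate_scored()` gives
planted edges scores uniform in `[boundary, 1]` and noise edges uniform in
`[0, boundary)`; `generate_annotations()` labels nodes by motif membership
(or permutes those labels for a null).

Study conditions used by the test suite (chosen once, as realistic
desk-scale analogues of the published experiments): the noise-sweep fixture
has 150 nodes and ~600 edges split across 3 cliques, 3 bicliques, and 4
stars plus 170 noise edges (~28% pre-noise), swept at fractions 0 and 0.6
with 10 replicates and ensembles of 30; the slicing fixture has 60 nodes,
a planted boundary of 0.8, and a 12-point quantile grid; the assortativity
ladder has 10 fixtures with noise rising from 10 to 145 edges on a fixed
planted structure; losslessness is checked over a 200-graph corpus; the
greedy-versus-oracle comparison covers graphs with up to 8 edges.

## Numerical and degenerate-input conventions

* The compression rate is undefined on an edgeless graph (error); sweep
  rows whose perturbed network drops below 2 edges are recorded as missing
  values so grids never abort.
* Local clustering of a node with fewer than 2 neighbors is 0 (the ratio is
  otherwise 0/0; an empty neighborhood subgraph is the natural reading).
* Reflexive power edges require at least 3 members (a 2-clique is a trivial
  edge; singleton self-adjacency is ignored by definition).
* All randomness flows through explicit integer seeds; the same seed
  reproduces every graph, ensemble, sweep, and matrix byte-for-byte.
* Node identifiers are case-sensitive text and are never normalized.

## Known limitations

* The greedy search has no optimality guarantee beyond the tested bound;
  compression rates are conservative estimates of the best achievable
  reduction.
* Relative rates inherit ensemble sampling error (reported as
  `ensemble_sd`); comparisons between networks closer than about
  $2\,sd/\sqrt{n}$ are not meaningful at small `n_random`.
* The brute-force oracle is exponential and unusable beyond ~10 edges, so
  optimality is only verified on tiny graphs.
* Compression of very sparse networks is of limited interest: a network of
  isolated edges is incompressible by construction, and its relative rate
  is exactly zero.
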
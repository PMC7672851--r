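---
title: "Aligning protein-protein interaction networks with ppinalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning protein-protein interaction networks with ppinalign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppinalign)
```

## The model

A protein-protein interaction network (PPIN) is an undirected simple
graph: proteins as nodes, physical interactions as edges. Given two PPINs
G = (V, E) and G' = (V', E') with |V| <= |V'|, the aligner produces an
injective partial map mu: V -> V' intended to send interacting proteins
onto interacting proteins (topological coherence) while matching proteins
of similar sequence (biological coherence). The method is parameter-free:
every threshold it uses is derived from the data itself.

The only biological input besides the graphs is sequence similarity,
consumed as precomputed BLAST bit scores. Each of the three tables
(within G, within G', cross-network) is rescaled to [0, 1] by its own
maximum, written B(u, v). Dividing by the per-table maximum is one of
several defensible normalizations; it guarantees B in [0, 1] with at
least one pair at 1 and needs no knowledge of the BLAST search-space
size. Because each table is normalized independently, absolute bit-score
magnitudes are not comparable across tables -- only the pipeline's use of
them (within-table ranking, cross-table positivity) is meaningful.

## The pipeline and its assumptions

**Step 1 -- overlapping clustering.** Node similarity within one network
combines sequence and proximity:

$$s(u,v) = \frac{B(u,v) + \frac{D+1 - d(u,v)}{D+1}}{2}$$

for nodes connected at hop distance d(u, v) in a network of diameter D
(the largest finite hop distance), and s(u, v) = 0 for disconnected
pairs. The threshold alpha is the third quartile of the s-values over
*all* unordered pairs of distinct nodes -- disconnected pairs contribute
their zeros, self-pairs are excluded -- so that at most 25% of pairs
satisfy s > alpha (ties sitting exactly at alpha are excluded by the
strict inequality, which is why "at most" rather than "exactly"). We use
linear interpolation between order statistics (R's default quantile,
type 7). The cluster centered at u is every v with s(u, v) > alpha, with
the center force-included even when its self-similarity does not clear
the threshold: the cluster alignment below unconditionally seeds at the
center pair, so the center must be a member. There is exactly one cluster
per node; clusters overlap freely.

**Step 2 -- cluster-pair alignment.** For each pair of centers (u, u')
with positive cross score B(u, u') > 0, the clusters are aligned
center-outward. The matching cost for candidate members is

$$F(v, v') = |\deg(v) - \deg(v')| - B(v, v') + 1,$$

with degrees taken in the full networks (not restricted to the cluster)
and B the normalized cross score; F >= 1 - B >= 0. The expansion is
queue-driven: at iteration k the k-th matched pair (v0, v0') is expanded
by a minimum-cost assignment between the unmatched cluster members
adjacent to v0 and those adjacent to v0'. New pairs are appended in
decreasing F order -- the literal reading of the procedure; since the
queue itself already layers candidates by distance from the center, this
sort only orders pairs within a layer, and an internal switch
(`expand_order`) implements the increasing alternative. Ties break
lexicographically, and candidate pairs with B = 0 are allowed (only the
*center* pair must have positive score). The result eta is injective,
fixes the centers, and every matched source node reaches the center
through previously matched intermediates.

**Step 3 -- matching the clusterings.** Each cluster alignment is scored

$$\mathrm{Score}(\eta) = \frac{\sum_{v \in \mathrm{Dom}\,\eta} B(v, \eta(v))}{|\mathrm{Dom}\,\eta|} + \frac{|\mathrm{Dom}\,\eta|}{\max_{\eta'} |\mathrm{Dom}\,\eta'|} \in (0, 2],$$

rewarding sequence similarity and coverage simultaneously; the
normalizing maximum domain size is computed once over all Step-2
alignments. A maximum-weight bipartite matching between the two cluster
families (edges = scored alignments) selects at most one partner per
cluster.

**Steps 4 and 5 -- consensus and extension.** The selected cluster
alignments may disagree on shared nodes. Each is viewed as a hyperarc
from its domain to its image, weighted by its score. Rather than merging
all of them, a *best-scored subset* is chosen greedily: repeatedly take
the highest-scoring matched alignment whose source center is not yet
covered by the selected domains, until every node occurring in any
matched domain is covered. (If a node remains uncovered but no eligible
alignment is left -- possible when its cluster went unmatched in Step 3
-- the loop stops; the extension rounds get further chances at it.) The
weighted bipartite hypergraph assignment problem is NP-hard, and we
resolve the conflicts greedily: hyperarcs in decreasing weight, and
within each arc every pair whose source and target are both unassigned
is accepted. An exhaustive assignment enumeration over arc subsets exists
in the test suite as an oracle for small instances. The extension then
iterates the whole consensus machinery on the residual problem:
restrict every Step-2 alignment to pairs with both endpoints unaligned,
rescore the restrictions (a restriction keeps a positive score exactly
when its domain is non-empty), re-match, re-select, re-merge. Pairs
fixed earlier are never revisited; each round fixes at least one new
pair, so at most |V| rounds can occur and the implementation treats more
as an internal error rather than looping.

The pair summary reported with the alignment -- its edge correctness and
the mean matched cross bit score -- is this package's concretization of
an overall similarity score for the two networks; it is descriptive
output, not an input to the algorithm.

## Evaluation statistics

* `edge_correctness`: preserved source edges over min(|E|, |E'|), in [0, 1].
* `functional_similarity` (FS): Jaccard index of GO term sets. Two
  unannotated proteins score 0 rather than an undefined 0/0: FS feeds an
  average, and crediting missing annotation would inflate it.
* `functional_coherence` (FC): mean FS over *all* source nodes (unmapped
  nodes contribute 0), so low coverage is penalized.
* `fc_max`: the best FC any injective map could achieve, by
  maximum-weight bipartite matching on the FS weights; FC <= FC_max
  always.
* `complex_coherence` (CFC): each source complex maps to the target
  complex receiving the plurality of its aligned members (ties:
  lexicographically first id; no aligned member: not assigned); an
  assigned pair is coherent when the complexes share a function label,
  and CFC = 100·CP/(CP + NCP). The plurality rule is our concretization
  of the usual complex-mapping procedure.
* `essentiality_metrics`: the alignment as a binary classifier of
  essentiality, with TP = essential source mapped to essential target,
  FP = essential to non-essential, TN/FN their complements, so P = TP+FP
  and N = TN+FN count mapped essential and non-essential source
  proteins. Unmapped proteins are excluded: the alignment makes no
  prediction for them. Precision is TP/(TP+FP) -- the standard
  definition. MCC uses the usual product-denominator formula and is
  reported as 0 with a flag when a margin vanishes; the uncertainty
  coefficient UC = (H(X) - H(X|Y))/H(X) uses base-2 entropies with the
  0·log 0 = 0 convention and is an error when H(X) = 0 (a constant
  essentiality vector cannot be predicted better or worse).

## The synthetic generator

`generate_pair(n1, n2, overlap, edge_density, noise, seed)` emulates the
situation the aligner faces in practice, with a known answer planted:

* Both networks are connected: a random recursive tree plus uniformly
  sampled extra edges up to `round(density * choose(n, 2))` edges.
  Connectivity is by construction, not by retry.
* A fraction `overlap` of net1's proteins get a true counterpart in
  net2; the subgraph induced by those proteins is copied through the
  correspondence, then net2 is padded with its own extra nodes/edges.
* Cross-network bit scores concentrate on true pairs (raw 80-100).
  `noise` adds `floor(10 * noise * n1)` spurious entries at a low floor
  (raw 0-40), so a true pair always exceeds the spurious mean -- the
  regime where bit scores are informative but not clean.
* Within-network tables put self-scores at the maximum (a protein is
  maximally similar to itself), moderate scores (20-80) on interacting
  pairs and a thin tail of random pairs (0-40), giving Step 1 a
  non-trivial sequence term.
* Each protein carries 3 GO terms; a counterpart inherits each term with
  probability 1 - noise.

`perturb_edges(net, f, seed)` implements the edge-noise protocol used in
robustness studies: delete `floor(f |E|)` random edges and add the same
number of absent ones (sampled from the complement of the original edge
set, so the symmetric difference is exactly `2 floor(f |E|)`); a
complete graph therefore cannot be perturbed and raises an error.

What the generator does *not* emulate: the heavy-tailed degree
distributions of real interactomes, correlated false negatives from
study bias, homology families (paralogs with near-identical bit scores),
or the GO DAG's term hierarchy. Passing the recovery tests therefore
shows the pipeline is correct and self-consistent, not that it attains
any particular accuracy on real interactomes.

## Numerical choices and determinism

* All iteration orders are lexicographic in the (opaque, case-sensitive)
  protein identifiers; every optimizer tie is broken deterministically,
  so results are invariant under permutations of the input edge lists.
* Minimum-cost assignment and all maximum-weight bipartite matchings are
  delegated to igraph's weighted bipartite matcher. The rectangular
  min-cost case is transformed to weights `K - cost` with
  `K = 2 * sum |cost| + 1`, large enough that cardinality dominates, so
  the optimum is a full-size min-cost assignment. Test oracles use
  exhaustive enumeration instead.
* Generators take explicit seeds, restore the caller's RNG state, and
  are byte-reproducible for a fixed seed.
* Degenerate inputs: empty edge files, all-zero bit-score tables,
  alignment of networks with no positive cross score (empty alignment
  with a warning), edgeless networks in edge correctness, and constant
  essentiality vectors are all rejected or flagged explicitly rather
  than returning silent NaNs.

## Problem sizes

The examples and tests run at 8-500 nodes; alignment instances of 100
nodes complete in about a second, and the clustering law (one cluster
per node, at most 25% of pairs above alpha) is exercised at n = 500. The
similarity matrix is dense, so memory grows as O(n^2); aligning
interactome-scale networks (10^4 nodes) is feasible but benefits from
caching the similarity matrices.

## A small session

```{r example}
sp <- generate_pair(n1 = 30, n2 = 36, overlap = 0.9, edge_density = 0.15,
                    noise = 0.2, seed = 7)
al <- ppin_align(sp$net1, sp$net2, sp$bits11, sp$bits22, sp$bits12)
al

m <- alignment_map(al)
mean(m[names(sp$truth)] == sp$truth, na.rm = TRUE)  # planted-pair recovery

functional_coherence(al, sp$ann1, sp$ann2, length(ppin_nodes(sp$net1)))
fc_max(sp$ann1, sp$ann2, ppin_nodes(sp$net1), ppin_nodes(sp$net2))
```

## Known limitations

* The hypergraph assignment is greedy, not exact; a heavier hyperarc
  always wins locally even when a lighter combination would cover more.
* Per-table max-normalization makes B values incomparable across tables
  and sensitive to a single outlier hit.
* The clustering quantile is taken over all pairs including disconnected
  ones; on very fragmented networks alpha collapses toward 0 and
  clusters grow large.
* Only undirected, unweighted networks are supported; k-way alignment is
  out of scope.
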
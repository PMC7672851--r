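# ppinalign

Parameter-free pairwise global alignment of protein–protein interaction
networks (PPINs), with the standard evaluation statistics and a synthetic
benchmark generator.

## The problem

A PPIN is an undirected graph G = (V, E) whose nodes are proteins and whose
edges are physical interactions. Aligning two PPINs — finding an injective
map μ : V → V′ from the smaller network into the larger — is a standard
route to transferring functional annotation and detecting conserved
interaction modules across species. The perennial difficulty is balancing
*topological* agreement (mapped interactions should land on interactions)
against *biological* agreement (mapped proteins should have similar
sequences and functions), and most aligners expose that balance as a
user-chosen parameter. `ppinalign` implements a pipeline that takes no
tunable algorithmic parameters at all.

## The method

Inputs are the two edge lists plus three BLAST bit-score tables (within
each network and across them), each rescaled to [0, 1] by its own maximum
to give normalized scores B(u, v).

1. **Overlapping clustering.** Within a network of diameter D, node
   similarity is
   `s(u,v) = ( B(u,v) + (D + 1 − d(u,v)) / (D + 1) ) / 2`
   for connected nodes at hop distance d, and 0 otherwise. With α the third
   quartile of the s-values over all node pairs (so at most 25% of pairs
   exceed it), the cluster centered at u is `C_u = { v : s(u,v) > α }` —
   one cluster per node, overlapping by construction.
2. **Cluster-pair alignment.** For every pair of centers with B(u, u′) > 0
   the two clusters are aligned center-outward: the not-yet-matched members
   adjacent to the most recently expanded pair are matched by a minimum-cost
   assignment under `F(v,v′) = |deg(v) − deg(v′)| − B(v,v′) + 1`, appended
   worst-cost-first, and the expansion queue advances until exhausted. The
   result is a partial injective map η between the clusters.
3. **Clustering match.** Each η is scored by its mean cross bit score plus
   its relative coverage, `Score(η) = mean B over Dom η + |Dom η| / max |Dom|`,
   and a maximum-weight bipartite matching selects one target cluster per
   source cluster.
4. **Local alignment.** A greedy best-scored subset of the matched cluster
   alignments (each viewed as a weighted hyperarc from its domain to its
   image) is merged into one consistent partial map: hyperarcs are
   processed by decreasing score, pairs whose endpoints are both free are
   accepted.
5. **Global extension.** Alignments are restricted to still-unaligned
   nodes, rescored, re-matched and re-merged, until no alignment retains a
   positive updated score. Every protein fixed earlier stays fixed.

Evaluation statistics: edge correctness `EC`, GO-based functional
similarity `FS` (Jaccard) and coherence `FC` with its attainable maximum
`FC_max`, complex functional coherence `CFC = 100·CP/(CP+NCP)`, complex
precision, and essential-protein classifier metrics (specificity,
precision, F1, accuracy, balanced accuracy, MCC, uncertainty coefficient).

## Worked example

Generate a 40-vs-50-node pair with an 80% planted correspondence and some
bit-score/annotation noise, align, and evaluate:

```r
library(ppinalign)
sp <- generate_pair(n1 = 40, n2 = 50, overlap = 0.8, edge_density = 0.12,
                    noise = 0.2, seed = 42)
al <- ppin_align(sp$net1, sp$net2, sp$bits11, sp$bits22, sp$bits12)
al
#> PPIN alignment synthetic-1 -> synthetic-2: 40 pairs (34 local)
#>   edge correctness 0.6489, mean matched bit score 0.6211

m <- alignment_map(al)
sum(m[names(sp$truth)] == sp$truth, na.rm = TRUE)   # 27 of 32 planted pairs
functional_coherence(al, sp$ann1, sp$ann2, 40)       # 0.4725
fc_max(sp$ann1, sp$ann2, ppin_nodes(sp$net1), ppin_nodes(sp$net2))  # 0.575
head(al$global, 4)
#>   source target stage
#> 1  s0025  t0008 local
#> 2  s0020  t0041 local
#> 3  s0022  t0028 local
#> 4  s0002  t0017 local
```

All 40 source proteins are aligned; 34 pairs were fixed by the local stage
and the rest during extension. The alignment preserves 64.9% of the
source interactions and recovers 27 of the 32 planted counterparts
despite 20% noise; its functional coherence (0.47) sits below the best
attainable value for these annotation tables (0.58), as it must.

A command-line front end covering the same pipeline lives at
`inst/cli/ppinalign.R` (subcommands `synth`, `align`, `eval`, `perturb`).

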
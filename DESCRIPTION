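Package: ppinalign
Title: Parameter-Free Pairwise Global Alignment of Protein-Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aligns two protein-protein interaction networks without
    tunable parameters.  An overlapping clustering of each network is
    built from a similarity score that combines normalized BLAST bit
    scores with graph proximity; clusters are aligned pairwise by
    center-outward iterated minimum-cost assignment, the two clusterings
    are matched by maximum-weight bipartite matching, and the selected
    cluster alignments are merged through a greedy weighted hypergraph
    assignment and iteratively extended to a consistent global
    alignment.  Includes the standard evaluation statistics for network
    alignments (edge correctness, GO-based functional coherence and its
    attainable maximum, complex functional coherence, essential-protein
    classifier metrics) and a synthetic generator of network pairs with
    a planted node correspondence for validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
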
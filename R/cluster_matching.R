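#' Score of a cluster alignment
#'
#' Balances sequence similarity and coverage:
#' the average normalized cross bit score over the matched source nodes,
#' plus the domain size normalized by the largest domain among all computed
#' cluster alignments. Lies in `(0, 2]`; the largest-domain alignment gets
#' a size term of exactly 1.
#'
#' @param a a [align_cluster_pair()] result.
#' @param bits12 cross-network [bit_score_table] (normalized; a raw table
#'   is normalized on the fly).
#' @param maxdom size of the largest domain among the alignments under
#'   consideration; must be at least `|Dom a|`.
#' @return Numeric score.
#' @export
score_alignment <- function(a, bits12, maxdom) {
  stopifnot(inherits(a, "cluster_alignment"))
  bits12 <- normalize_bit_scores(bits12)
  ndom <- length(a$eta)
  if (ndom < 1L) stop("cluster alignment has an empty domain")
  stopifnot(maxdom >= ndom)
  mean(bit_score(bits12, names(a$eta), unname(a$eta))) + ndom / maxdom
}

#' Maximum-weight matching between two clusterings
#'
#' Selects a one-to-one matching between the clusters of the two networks
#' (each cluster identified by its center) maximizing the total alignment
#' score, via maximum-weight bipartite matching. Edges are the scored
#' cluster alignments.
#'
#' @param edges data frame with columns `source`, `target` (cluster
#'   centers) and `score` (positive weights).
#' @return Data frame, a subset of `edges` rows forming the selected
#'   matching, ordered by `source`. Empty input gives an empty matching.
#' @export
match_clusterings <- function(edges) {
  empty <- data.frame(source = character(0), target = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) return(empty)
  stopifnot(all(c("source", "target", "score") %in% names(edges)))
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  su <- sort(unique(edges$source))
  tv <- sort(unique(edges$target))
  nr <- length(su)
  types <- c(rep(FALSE, nr), rep(TRUE, length(tv)))
  i <- match(edges$source, su)
  j <- nr + match(edges$target, tv)
  g <- igraph::make_bipartite_graph(types, as.vector(rbind(i, j)))
  igraph::E(g)$weight <- edges$score
  match <- suppressWarnings(igraph::max_bipartite_match(g))$matching
  sel_i <- which(!is.na(match[seq_len(nr)]))
  key <- paste(edges$source, edges$target, sep = "\r")
  sel <- match(paste(su[sel_i], tv[match[sel_i] - nr], sep = "\r"), key)
  out <- edges[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}
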
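#' Node similarity within one network
#'
#' Two proteins of the same network are considered similar when their
#' sequences are similar (normalized bit score `B`) and they are close in
#' the interaction graph. For connected nodes at hop distance `d` in a
#' network of diameter `D`,
#'
#'   `s(u,v) = ( B(u,v) + (D + 1 - d(u,v)) / (D + 1) ) / 2`
#'
#' and `s(u,v) = 0` for nodes in different connected components. Values lie
#' in `[0,1]`; the distance term alone gives any connected pair a floor of
#' `1 / (2 (D + 1))`.
#'
#' @param u,v node identifiers.
#' @param net a [ppin].
#' @param bits the within-network [bit_score_table] (normalized; a raw
#'   table is normalized on the fly).
#' @return Similarity in `[0,1]`.
#' @export
node_similarity <- function(u, v, net, bits) {
  sim <- similarity_matrix(net, bits)
  sim$s[u, v]
}

#' Similarity matrix and quartile threshold of a network
#'
#' Computes `s(u,v)` for every node pair of the network along with the
#' clustering threshold `alpha`: the third quartile of the similarity values
#' over all unordered pairs of distinct nodes (disconnected pairs contribute
#' their 0), so that at most 25% of pairs satisfy `s > alpha`.
#'
#' @inheritParams node_similarity
#' @return An object of class `ppin_similarity`: list with the dense
#'   symmetric matrix `s`, the threshold `alpha`, and the diameter used.
#' @export
similarity_matrix <- function(net, bits) {
  stopifnot(inherits(net, "ppin"), inherits(bits, "bit_score_table"))
  bits <- normalize_bit_scores(bits)
  nodes <- ppin_nodes(net)
  d <- ppin_distances(net)
  D <- max(0, d[is.finite(d)])
  B <- bit_score_dense(bits, nodes, nodes)
  s <- (B + (D + 1 - d) / (D + 1)) / 2
  s[!is.finite(d)] <- 0
  vals <- s[upper.tri(s)]
  structure(
    list(s = s, alpha = quartile_threshold(vals), diameter = D),
    class = "ppin_similarity"
  )
}

#' @export
print.ppin_similarity <- function(x, ...) {
  cat(sprintf("similarity matrix: %d nodes, diameter %g, alpha = %.4f\n",
              nrow(x$s), x$diameter, x$alpha))
  invisible(x)
}

#' Third-quartile threshold of a similarity distribution
#'
#' Linear interpolation between order statistics (R's default quantile
#' convention, type 7). By construction at most 25% of the values strictly
#' exceed the returned threshold.
#'
#' @param values numeric vector of similarity values (at least one).
#' @return The 0.75 quantile.
#' @export
quartile_threshold <- function(values) {
  if (length(values) == 0L) stop("no similarity values: cannot take quartile")
  stats::quantile(values, 0.75, names = FALSE, type = 7)
}

#' Overlapping clustering of a network
#'
#' One cluster per node: the cluster centered at `u` contains every node `v`
#' with `s(u,v) > alpha` (strict), plus the center itself. Centers are
#' always members because every downstream cluster alignment is seeded at
#' the center pair.
#'
#' @param net a [ppin].
#' @param sim a `ppin_similarity` from [similarity_matrix()].
#' @return A named list of class `ppin_clustering`: center -> sorted
#'   character vector of members.
#' @examples
#' sp <- generate_pair(8, 9, edge_density = 9 / 28, seed = 1)
#' sim <- similarity_matrix(sp$net1, sp$bits11)
#' length(build_clustering(sp$net1, sim))  # 8: one cluster per node
#' @export
build_clustering <- function(net, sim) {
  stopifnot(inherits(net, "ppin"), inherits(sim, "ppin_similarity"))
  nodes <- ppin_nodes(net)
  stopifnot(identical(rownames(sim$s), nodes))
  out <- lapply(nodes, function(u) {
    sort(unique(c(u, nodes[sim$s[u, ] > sim$alpha])))
  })
  names(out) <- nodes
  structure(out, class = "ppin_clustering")
}

#' @export
print.ppin_clustering <- function(x, ...) {
  cat(sprintf("overlapping clustering: %d clusters, sizes %d-%d (median %g)\n",
              length(x), min(lengths(x)), max(lengths(x)),
              stats::median(lengths(x))))
  invisible(x)
}
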
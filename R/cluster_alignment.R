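#' Neighbor-matching cost
#'
#' Cost of matching node `v` of the first network with node `v2` of the
#' second while expanding a cluster alignment:
#'
#'   `F(v, v2) = |deg(v) - deg(v2)| - B(v, v2) + 1`
#'
#' with full-network degrees and the normalized cross-network bit score.
#' Since `B <= 1`, the cost is always non-negative; degree twins with
#' maximal sequence similarity cost 0.
#'
#' @param v,v2 node identifiers in `net1` and `net2`.
#' @param net1,net2 [ppin] objects.
#' @param bits12 cross-network [bit_score_table] (normalized; a raw table
#'   is normalized on the fly).
#' @return Numeric cost.
#' @export
neighbor_cost <- function(v, v2, net1, net2, bits12) {
  bits12 <- normalize_bit_scores(bits12)
  abs(ppin_degree(net1)[v] - ppin_degree(net2)[v2]) -
    bit_score(bits12, v, v2) + 1
}

#' Minimum-cost assignment between two node sets
#'
#' Solves the (possibly rectangular) assignment problem for a cost matrix:
#' a matching of size `min(nrow, ncol)` with minimum total cost, computed
#' as a maximum-weight bipartite matching on transformed weights large
#' enough that full cardinality always dominates.
#'
#' @param cost numeric matrix with row and column names.
#' @return Data frame with columns `row`, `col`, `cost`, one matched pair
#'   per line, ordered by row name. Empty if either side is empty.
#' @examples
#' m <- matrix(c(1, 2, 2, 4), 2, byrow = TRUE,
#'             dimnames = list(c("r1", "r2"), c("c1", "c2")))
#' min_cost_matching(m)  # r1-c2, r2-c1: total 4 beats the diagonal's 5
#' @export
min_cost_matching <- function(cost) {
  empty <- data.frame(row = character(0), col = character(0),
                      cost = numeric(0), stringsAsFactors = FALSE)
  if (is.null(dim(cost)) || nrow(cost) == 0L || ncol(cost) == 0L) {
    return(empty)
  }
  rows <- rownames(cost) %||% paste0("r", seq_len(nrow(cost)))
  cols <- colnames(cost) %||% paste0("c", seq_len(ncol(cost)))
  nr <- length(rows)
  nc <- length(cols)
  # shift so that adding any edge to a matching always increases the total
  # weight: guarantees maximum cardinality
  K <- 2 * sum(abs(cost)) + 1
  types <- c(rep(FALSE, nr), rep(TRUE, nc))
  ij <- as.matrix(expand.grid(i = seq_len(nr), j = seq_len(nc)))
  edges <- rbind(ij[, 1L], nr + ij[, 2L])
  g <- igraph::make_bipartite_graph(types, as.vector(edges))
  igraph::E(g)$weight <- K - cost[ij]
  match <- suppressWarnings(igraph::max_bipartite_match(g))$matching
  i <- which(!is.na(match[seq_len(nr)]))
  j <- match[i] - nr
  out <- data.frame(row = rows[i], col = cols[j],
                    cost = cost[cbind(i, j)], stringsAsFactors = FALSE)
  out[order(out$row), , drop = FALSE]
}

#' Align a pair of clusters center-outward
#'
#' Seeds the alignment at the two centers (which requires a positive cross
#' bit score between them) and grows it outward: at iteration `k` the k-th
#' matched pair `(v0, v0')` is expanded by solving a minimum-cost
#' assignment, over the `F` costs, between the not-yet-matched cluster
#' members adjacent to `v0` and those adjacent to `v0'`. The new pairs are
#' appended in decreasing order of their `F` value (ties by source then
#' target identifier) and the loop ends when every pair in the list has
#' been expanded. Every matched source node is thus connected to the center
#' through previously matched intermediates.
#'
#' @param u,u2 cluster centers in `net1` and `net2`.
#' @param clustering1,clustering2 [build_clustering()] results for the two
#'   networks.
#' @param net1,net2 [ppin] objects.
#' @param bits12 cross-network [bit_score_table].
#' @return An object of class `cluster_alignment`: list with `source`,
#'   `target` (the centers), `pairs` (data frame `source`, `target`, `F`
#'   in match order; the seed pair has `F = NA`), and `eta` (named
#'   character vector, the induced partial injective map). `NULL` when the
#'   centers have no positive cross score (the pair is not alignable).
#' @export
align_cluster_pair <- function(u, u2, clustering1, clustering2,
                               net1, net2, bits12) {
  bits12 <- normalize_bit_scores(bits12)
  ctx <- list(
    deg1 = ppin_degree(net1), deg2 = ppin_degree(net2),
    adj1 = ppin_adjacency(net1), adj2 = ppin_adjacency(net2),
    B = bit_score_dense(bits12, ppin_nodes(net1), ppin_nodes(net2))
  )
  align_cluster_pair_ctx(ctx, u, u2, clustering1[[u]], clustering2[[u2]])
}

# Work-horse shared with the pipeline, which precomputes ctx once.
# expand_order = "decreasing" appends each iteration's pairs worst-F-first,
# the literal reading of the procedure; "increasing" is the alternative.
align_cluster_pair_ctx <- function(ctx, u, u2, members1, members2,
                                   expand_order = "decreasing") {
  if (ctx$B[u, u2] <= 0) return(NULL)
  src <- u
  tgt <- u2
  fval <- NA_real_
  k <- 1L
  while (k <= length(src)) {
    v0 <- src[k]
    v0p <- tgt[k]
    rows <- setdiff(intersect(members1, ctx$adj1[[v0]]), src)
    cols <- setdiff(intersect(members2, ctx$adj2[[v0p]]), tgt)
    if (length(rows) > 0L && length(cols) > 0L) {
      rows <- sort(rows)
      cols <- sort(cols)
      cost <- abs(outer(ctx$deg1[rows], ctx$deg2[cols], `-`)) -
        ctx$B[rows, cols, drop = FALSE] + 1
      dimnames(cost) <- list(rows, cols)
      m <- min_cost_matching(cost)
      if (nrow(m) > 0L) {
        o <- if (identical(expand_order, "decreasing")) {
          order(-m$cost, m$row, m$col)
        } else {
          order(m$cost, m$row, m$col)
        }
        src <- c(src, m$row[o])
        tgt <- c(tgt, m$col[o])
        fval <- c(fval, m$cost[o])
      }
    }
    k <- k + 1L
  }
  structure(
    list(
      source = u, target = u2,
      pairs = data.frame(source = src, target = tgt, F = fval,
                         stringsAsFactors = FALSE),
      eta = stats::setNames(tgt, src)
    ),
    class = "cluster_alignment"
  )
}

#' @export
print.cluster_alignment <- function(x, ...) {
  cat(sprintf("cluster alignment %s -> %s: %d matched pairs\n",
              x$source, x$target, length(x$eta)))
  invisible(x)
}
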
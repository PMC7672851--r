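#' Synthetic network pairs with a planted correspondence
#'
#' Generates a pair of connected PPINs in which a chosen fraction of the
#' smaller network's proteins have a true counterpart in the larger one: the
#' subgraph induced by the planted correspondence is copied into the second
#' network, which is then padded with extra proteins and interactions to its
#' own size. Cross-network bit scores are concentrated on the true pairs
#' (raw scores in 80-100) with, for `noise > 0`, additional spurious entries
#' on random non-pairs at a low floor (0-40), so that true pairs always
#' exceed the floor. GO term sets are inherited across the correspondence,
#' each term being replaced with a random one with probability `noise`.
#' Within-network tables always carry maximal self-scores, plus moderate
#' scores on interacting and a few random pairs.
#'
#' Everything is deterministic for a fixed `seed`, and the caller's RNG
#' state is left untouched.
#'
#' @param n1,n2 node counts, `2 <= n1 <= n2`.
#' @param overlap fraction of net1 nodes with a true counterpart in net2.
#' @param edge_density target fraction of realized node pairs (at least a
#'   spanning tree is always present).
#' @param noise noise level in `[0,1]` controlling spurious bit-score
#'   entries and annotation corruption.
#' @param seed integer seed.
#' @return An object of class `synthetic_pair`: list with `net1`, `net2`
#'   ([ppin]), `truth` (named character vector, net1 node -> net2 node),
#'   `bits11`, `bits22`, `bits12` ([bit_score_table], raw scale), `ann1`,
#'   `ann2` ([annotation_table]) and `seed`.
#' @examples
#' sp <- generate_pair(8, 9, overlap = 1, edge_density = 9 / 28, seed = 1)
#' length(ppin_nodes(sp$net1))  # 8
#' @export
generate_pair <- function(n1, n2, overlap = 1, edge_density = 0.15,
                          noise = 0, seed = 1) {
  stopifnot(n1 >= 2, n1 <= n2,
            overlap >= 0, overlap <= 1,
            edge_density >= 0, edge_density <= 1,
            noise >= 0, noise <= 1)
  with_seed(seed, {
    width <- max(4L, nchar(as.character(n2)))
    nodes1 <- sprintf(paste0("s%0", width, "d"), seq_len(n1))
    nodes2 <- sprintf(paste0("t%0", width, "d"), seq_len(n2))

    e1 <- random_connected_edges(nodes1, edge_density)
    net1 <- ppin(e1, name = "synthetic-1", nodes = nodes1)

    n_map <- floor(overlap * n1)
    truth <- stats::setNames(character(0), character(0))
    if (n_map > 0L) {
      src <- sort(sample(nodes1, n_map))
      tgt <- sample(nodes2, n_map)
      truth <- stats::setNames(tgt, src)
    }

    # copy the truth-induced subgraph into net2, then pad to target density
    e2 <- matrix(character(0), ncol = 2L)
    if (n_map > 0L && nrow(e1) > 0L) {
      sel <- e1[, 1L] %in% names(truth) & e1[, 2L] %in% names(truth)
      if (any(sel)) {
        e2 <- cbind(unname(truth[e1[sel, 1L]]), unname(truth[e1[sel, 2L]]))
      }
    }
    m2_target <- max(n2 - 1L, round(edge_density * n2 * (n2 - 1) / 2), nrow(e2))
    m2_target <- min(m2_target, n2 * (n2 - 1) / 2)
    extra <- m2_target - nrow(e2)
    if (extra > 0L) {
      e2 <- rbind(e2, sample_absent_edges(nodes2, pair_key(e2[, 1L], e2[, 2L]),
                                          extra))
    }
    e2 <- connect_components(nodes2, e2)
    net2 <- ppin(e2, name = "synthetic-2", nodes = nodes2)

    bits12 <- cross_bit_scores(nodes1, nodes2, truth, noise)
    bits11 <- within_bit_scores(net1)
    bits22 <- within_bit_scores(net2)

    pool <- sprintf("T%05d", seq_len(2L * n2))
    ann <- synthetic_annotations(nodes1, nodes2, truth, noise, pool)

    structure(
      list(net1 = net1, net2 = net2, truth = truth,
           bits11 = bits11, bits22 = bits22, bits12 = bits12,
           ann1 = ann$ann1, ann2 = ann$ann2, seed = seed),
      class = "synthetic_pair"
    )
  })
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf(
    "synthetic PPIN pair (seed %s): %d vs %d nodes, %d planted pairs\n",
    format(x$seed), length(x$net1$nodes), length(x$net2$nodes),
    length(x$truth)
  ))
  invisible(x)
}

#' Perturb a network by deleting and adding a fraction of its edges
#'
#' Deletes `floor(fraction * |E|)` uniformly chosen existing edges and adds
#' the same number of uniformly chosen absent (non-loop) edges, sampled
#' from the complement of the original edge set so that the symmetric
#' difference between the old and new edge sets is exactly twice the
#' deletion count. The node set is unchanged.
#'
#' @param x a [ppin] object.
#' @param fraction fraction of edges to rewire, in `[0,1]`.
#' @param seed integer seed.
#' @return A new [ppin] with the perturbed edge set.
#' @export
perturb_edges <- function(x, fraction, seed = 1) {
  stopifnot(inherits(x, "ppin"), fraction >= 0, fraction <= 1)
  e <- ppin_edges(x)
  k <- floor(fraction * nrow(e))
  if (k == 0L) return(ppin(e, name = x$name, nodes = x$nodes))
  n <- length(x$nodes)
  total <- n * (n - 1) / 2
  if (total - nrow(e) < k) {
    stop("perturbation infeasible: not enough absent edges to add")
  }
  with_seed(seed, {
    keep <- e[-sample(nrow(e), k), , drop = FALSE]
    added <- sample_absent_edges(x$nodes, pair_key(e[, 1L], e[, 2L]), k)
    ppin(rbind(keep, added), name = x$name, nodes = x$nodes)
  })
}

# ---- internal generators ----------------------------------------------------

# Connected random graph: random recursive tree plus uniformly sampled extra
# edges to reach round(density * choose(n,2)) edges.
random_connected_edges <- function(nodes, density) {
  n <- length(nodes)
  m <- max(n - 1L, round(density * n * (n - 1) / 2))
  m <- min(m, n * (n - 1) / 2)
  perm <- sample(nodes)
  anchors <- vapply(seq_len(n - 1L), function(i) {
    perm[sample.int(i, 1L)]
  }, "")
  tree <- cbind(anchors, perm[-1L])
  extra <- m - (n - 1L)
  if (extra > 0L) {
    tree <- rbind(tree,
                  sample_absent_edges(nodes, pair_key(tree[, 1L], tree[, 2L]),
                                      extra))
  }
  unname(tree)
}

# k absent non-loop edges among `nodes`, avoiding `existing_keys`.
# Enumerates the complement when the pair universe is small; otherwise
# rejection-samples with a bounded number of rounds.
sample_absent_edges <- function(nodes, existing_keys, k) {
  if (k <= 0L) return(matrix(character(0), ncol = 2L))
  n <- length(nodes)
  total <- n * (n - 1) / 2
  avail <- total - length(unique(existing_keys))
  if (avail < k) stop("not enough absent edges to sample")
  if (total <= 2e5) {
    idx <- utils::combn(sort(nodes), 2L)
    keys <- pair_key(idx[1L, ], idx[2L, ])
    free <- which(!(keys %in% existing_keys))
    pick <- free[sample(length(free), k)]
    return(cbind(idx[1L, pick], idx[2L, pick]))
  }
  have <- unique(existing_keys)
  out_a <- character(0)
  out_b <- character(0)
  for (round in 1:60) {
    a0 <- nodes[sample.int(n, 4L * k, replace = TRUE)]
    b0 <- nodes[sample.int(n, 4L * k, replace = TRUE)]
    ok <- a0 != b0
    a <- pmin(a0[ok], b0[ok])
    b <- pmax(a0[ok], b0[ok])
    key <- pair_key(a, b)
    new <- !(key %in% have) & !duplicated(key)
    out_a <- c(out_a, a[new])
    out_b <- c(out_b, b[new])
    have <- c(have, key[new])
    if (length(out_a) >= k) {
      return(cbind(out_a[seq_len(k)], out_b[seq_len(k)]))
    }
  }
  stop("edge sampling failed: graph too dense for rejection sampling")
}

# Add bridging edges between connected components until connected.
connect_components <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(g)$membership
  while (max(comp) > 1L) {
    pool_a <- names(comp)[comp == 1L]
    other <- setdiff(unique(comp), 1L)[1L]
    pool_b <- names(comp)[comp == other]
    a <- pool_a[sample.int(length(pool_a), 1L)]
    b <- pool_b[sample.int(length(pool_b), 1L)]
    edges <- rbind(edges, c(a, b))
    comp[comp == other] <- 1L
  }
  edges
}

# Cross-network raw bit scores: true pairs uniform in [80, 100]; for
# noise > 0, floor(noise * 10 * n1) spurious non-true pairs uniform in
# [0, 40]. A true pair therefore always beats the spurious mean (20).
cross_bit_scores <- function(nodes1, nodes2, truth, noise) {
  u <- names(truth)
  v <- unname(truth)
  s <- stats::runif(length(truth), 80, 100)
  n_noise <- floor(noise * 10 * length(nodes1))
  if (n_noise > 0L) {
    a <- nodes1[sample.int(length(nodes1), n_noise, replace = TRUE)]
    b <- nodes2[sample.int(length(nodes2), n_noise, replace = TRUE)]
    true_key <- pair_key(u, v)
    ok <- !(pair_key(a, b) %in% true_key)
    u <- c(u, a[ok])
    v <- c(v, b[ok])
    s <- c(s, stats::runif(sum(ok), 0, 40))
  }
  if (length(u) == 0L) {
    # degenerate overlap = 0 request: keep the table non-empty so that
    # normalization is defined, using a single arbitrary low entry
    u <- nodes1[1L]
    v <- nodes2[1L]
    s <- 1
  }
  bit_score_table(u, v, s)
}

# Within-network raw bit scores: self-scores at the maximum (100),
# interacting pairs at U(20, 80), plus n random pairs at U(0, 40).
within_bit_scores <- function(net) {
  nodes <- ppin_nodes(net)
  e <- ppin_edges(net)
  u <- c(nodes, e[, 1L])
  v <- c(nodes, e[, 2L])
  s <- c(rep(100, length(nodes)), stats::runif(nrow(e), 20, 80))
  n_rand <- length(nodes)
  a <- nodes[sample.int(length(nodes), n_rand, replace = TRUE)]
  b <- nodes[sample.int(length(nodes), n_rand, replace = TRUE)]
  ok <- a != b
  bit_score_table(c(u, a[ok]), c(v, b[ok]),
                  c(s, stats::runif(sum(ok), 0, 40)))
}

# Annotations: 3 terms per net1 node; true counterparts inherit each term
# with probability 1 - noise (corrupted terms are resampled), other net2
# nodes get 3 random terms.
synthetic_annotations <- function(nodes1, nodes2, truth, noise, pool) {
  k <- 3L
  t1 <- lapply(nodes1, function(u) sample(pool, k))
  names(t1) <- nodes1
  t2 <- lapply(nodes2, function(v) sample(pool, k))
  names(t2) <- nodes2
  for (u in names(truth)) {
    keep <- stats::runif(k) >= noise
    terms <- t1[[u]]
    terms[!keep] <- sample(pool, sum(!keep))
    t2[[truth[[u]]]] <- terms
  }
  list(
    ann1 = annotation_table(rep(nodes1, each = k), unlist(t1)),
    ann2 = annotation_table(rep(nodes2, each = k), unlist(t2))
  )
}
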
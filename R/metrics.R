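#' Edge correctness of an alignment
#'
#' Fraction of structure preserved: the number of source-network edges
#' whose two endpoints are mapped onto an edge of the target network,
#' divided by `min(|E|, |E'|)`.
#'
#' @param mu alignment: a `ppin_alignment`, an alignment data frame, or a
#'   named character vector (source -> target).
#' @param net1,net2 source and target [ppin]s.
#' @return Value in `[0,1]`.
#' @export
edge_correctness <- function(mu, net1, net2) {
  mu <- as_alignment_vector(mu)
  e1 <- ppin_edges(net1)
  e2 <- ppin_edges(net2)
  if (nrow(e1) == 0L || nrow(e2) == 0L) {
    stop("edge correctness undefined for an edgeless network")
  }
  a <- unname(mu[e1[, 1L]])
  b <- unname(mu[e1[, 2L]])
  ok <- !is.na(a) & !is.na(b)
  preserved <- sum(pair_key(a[ok], b[ok]) %in% pair_key(e2[, 1L], e2[, 2L]))
  preserved / min(nrow(e1), nrow(e2))
}

#' Functional similarity of two proteins
#'
#' Jaccard index of their GO term sets. Two unannotated proteins score 0
#' (the conservative choice, since the coherence score below averages
#' similarities).
#'
#' @param u,v protein identifiers.
#' @param ann1 [annotation_table] for `u`'s network.
#' @param ann2 [annotation_table] for `v`'s network (defaults to `ann1`).
#' @return Value in `[0,1]`.
#' @export
functional_similarity <- function(u, v, ann1, ann2 = ann1) {
  jaccard(go_terms(ann1, u), go_terms(ann2, v))
}

jaccard <- function(a, b) {
  un <- length(union(a, b))
  if (un == 0L) return(0)
  length(intersect(a, b)) / un
}

#' Functional coherence of an alignment
#'
#' Mean functional similarity of the aligned pairs over all `n_source`
#' proteins of the source network; unmapped proteins contribute 0.
#'
#' @inheritParams edge_correctness
#' @param ann1,ann2 [annotation_table]s of the source and target networks.
#' @param n_source number of proteins in the source network.
#' @return Value in `[0,1]`.
#' @export
functional_coherence <- function(mu, ann1, ann2, n_source) {
  mu <- as_alignment_vector(mu)
  stopifnot(n_source >= length(mu))
  if (n_source == 0L) return(0)
  fs <- vapply(seq_along(mu), function(i) {
    functional_similarity(names(mu)[i], mu[[i]], ann1, ann2)
  }, 0)
  sum(fs) / n_source
}

#' Maximum attainable functional coherence
#'
#' Best functional coherence over all injective maps between the two node
#' sets: a maximum-weight bipartite matching with the pairwise functional
#' similarities as weights, divided by the size of the smaller node set.
#' Puts observed coherence values in perspective.
#'
#' @param ann1,ann2 [annotation_table]s.
#' @param nodes1,nodes2 node sets of the two networks.
#' @return Value in `[0,1]`.
#' @export
fc_max <- function(ann1, ann2, nodes1, nodes2) {
  n <- min(length(nodes1), length(nodes2))
  if (n == 0L) return(0)
  fs <- outer(nodes1, nodes2, Vectorize(function(u, v) {
    functional_similarity(u, v, ann1, ann2)
  }))
  pos <- which(fs > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(0)
  nr <- length(nodes1)
  types <- c(rep(FALSE, nr), rep(TRUE, length(nodes2)))
  g <- igraph::make_bipartite_graph(
    types, as.vector(rbind(pos[, 1L], nr + pos[, 2L]))
  )
  igraph::E(g)$weight <- fs[pos]
  suppressWarnings(igraph::max_bipartite_match(g))$matching_weight / n
}

#' Complex functional coherence of an alignment
#'
#' Each source complex is mapped to the target complex receiving the
#' plurality of its aligned members (ties: lexicographically first complex
#' id; complexes with no aligned member are "not assigned"). An assigned
#' pair is coherent when the two complexes share at least one function
#' label. `CFC = 100 * CP / (CP + NCP)` over the coherent (`CP`) and
#' incoherent (`NCP`) assigned pairs.
#'
#' @inheritParams edge_correctness
#' @param complexes1,complexes2 [complex_catalog]s for the two networks.
#' @return List of class `complex_pair_table` with `not_assigned`, `cp`,
#'   `ncp` and `cfc`.
#' @export
complex_coherence <- function(mu, complexes1, complexes2) {
  mu <- as_alignment_vector(mu)
  stopifnot(inherits(complexes1, "complex_catalog"),
            inherits(complexes2, "complex_catalog"))
  ids2 <- names(complexes2)
  not_assigned <- 0L
  cp <- 0L
  ncp <- 0L
  for (cx in complexes1) {
    images <- unname(mu[cx$members])
    images <- images[!is.na(images)]
    if (length(images) == 0L) {
      not_assigned <- not_assigned + 1L
      next
    }
    votes <- vapply(complexes2, function(cy) {
      sum(images %in% cy$members)
    }, 0L)
    if (max(votes) == 0L) {
      not_assigned <- not_assigned + 1L
      next
    }
    best <- ids2[votes == max(votes)][1L]  # ids2 is sorted: lexicographic tie
    if (length(intersect(cx$labels, complexes2[[best]]$labels)) > 0L) {
      cp <- cp + 1L
    } else {
      ncp <- ncp + 1L
    }
  }
  if (cp + ncp == 0L) stop("no assigned complex pairs: CFC undefined")
  structure(
    list(not_assigned = not_assigned, cp = cp, ncp = ncp,
         cfc = complex_cfc(cp, ncp)),
    class = "complex_pair_table"
  )
}

#' @export
print.complex_pair_table <- function(x, ...) {
  cat(sprintf("complexes: %d not assigned, %d coherent, %d incoherent, CFC %.2f\n",
              x$not_assigned, x$cp, x$ncp, x$cfc))
  invisible(x)
}

#' CFC and complex precision from contingency counts
#'
#' `complex_cfc` computes `100 * cp / (cp + ncp)`;
#' `complex_precision` is the same ratio for the coherent/incoherent
#' counts of complexes aligned by one method but not another, reported as
#' a percentage.
#'
#' @param cp,ncp coherent and incoherent pair counts.
#' @return Percentage in `[0,100]`.
#' @export
complex_cfc <- function(cp, ncp) {
  if (cp + ncp <= 0) stop("CFC undefined: no assigned pairs")
  100 * cp / (cp + ncp)
}

#' @rdname complex_cfc
#' @param coherent,incoherent counts of coherent and incoherent pairs
#'   among the complexes aligned by one method only.
#' @export
complex_precision <- function(coherent, incoherent) {
  if (coherent + incoherent <= 0) stop("precision undefined: none assigned")
  100 * coherent / (coherent + incoherent)
}

#' Essential-protein classifier metrics of an alignment
#'
#' Treats the alignment as a predictor of essentiality: over the mapped
#' source proteins, `X` indicates an essential source protein and `Y` an
#' essential image. With the labeling
#' TP = essential -> essential, FP = essential -> non-essential,
#' TN = non-essential -> non-essential, FN = non-essential -> essential
#' (so `P = TP + FP` and `N = TN + FN` count essential and non-essential
#' mapped source proteins), it reports: specificity `TN/N`, precision
#' `TP/(TP+FP)`, F1 `2TP/(2TP+FP+FN)`, accuracy `(TP+TN)/(P+N)`, balanced
#' accuracy `((TP/P)+(TN/N))/2`, the Matthews correlation coefficient, and
#' the uncertainty coefficient `UC = (H(X) - H(X|Y))/H(X)` with entropies
#' in bits over the empirical joint distribution.
#'
#' @inheritParams edge_correctness
#' @param essential1,essential2 character vectors of essential proteins in
#'   the source and target networks.
#' @return List with the seven statistics plus the confusion counts. MCC
#'   is reported as 0 (with `mcc_degenerate = TRUE`) when its denominator
#'   vanishes; a constant `X` makes UC undefined and is an error.
#' @export
essentiality_metrics <- function(mu, essential1, essential2) {
  mu <- as_alignment_vector(mu)
  if (length(mu) == 0L) stop("empty alignment: no proteins to classify")
  x <- names(mu) %in% essential1
  y <- unname(mu) %in% essential2
  tp <- sum(x & y)
  fp <- sum(x & !y)
  tn <- sum(!x & !y)
  fn <- sum(!x & y)
  p <- tp + fp
  n <- tn + fn
  if (p == 0L || n == 0L) {
    stop("need both essential and non-essential mapped proteins")
  }
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc_degenerate <- denom == 0
  mcc <- if (mcc_degenerate) 0 else (tp * tn - fp * fn) / denom
  hx <- entropy_bits(table(x))
  if (hx == 0) stop("essentiality entropy is zero: UC undefined")
  hxy <- conditional_entropy_bits(x, y)
  list(
    specificity = tn / n,
    precision = tp / (tp + fp),
    f1 = 2 * tp / (2 * tp + fp + fn),
    accuracy = (tp + tn) / (p + n),
    balanced_accuracy = (tp / p + tn / n) / 2,
    mcc = mcc,
    uc = (hx - hxy) / hx,
    counts = list(tp = tp, fp = fp, tn = tn, fn = fn, p = p, n = n),
    mcc_degenerate = mcc_degenerate
  )
}

entropy_bits <- function(counts) {
  pr <- counts / sum(counts)
  pr <- pr[pr > 0]
  -sum(pr * log2(pr))
}

conditional_entropy_bits <- function(x, y) {
  out <- 0
  for (val in unique(y)) {
    sel <- y == val
    out <- out + mean(sel) * entropy_bits(table(x[sel]))
  }
  out
}

# Accept a ppin_alignment, a data frame, or a named vector.
as_alignment_vector <- function(mu) {
  if (inherits(mu, "ppin_alignment")) mu <- mu$global
  if (is.data.frame(mu)) mu <- stats::setNames(mu$target, mu$source)
  stopifnot(is.character(mu))
  if (length(mu) > 0L) stopifnot(!is.null(names(mu)))
  if (anyDuplicated(names(mu)) || anyDuplicated(mu)) {
    stop("alignment must be an injective map")
  }
  mu
}
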
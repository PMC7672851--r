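#' Greedy selection of best-scored cluster alignments
#'
#' From the matched cluster alignments, builds the subset used to form the
#' hypergraph: starting from the empty set, repeatedly add the
#' highest-scoring alignment whose source center is not yet covered by the
#' domains of the alignments already selected (score ties broken by source
#' then target center identifier), until every node appearing in any
#' candidate's domain is covered, or no eligible alignment remains.
#'
#' @param alignments list of [align_cluster_pair()] results (the matched
#'   set).
#' @param scores numeric vector of their scores, parallel to `alignments`.
#' @return The selected alignments, in insertion order.
#' @export
select_best_scored <- function(alignments, scores) {
  stopifnot(length(alignments) == length(scores))
  if (length(alignments) == 0L) return(list())
  centers <- vapply(alignments, function(a) a$source, "")
  targets <- vapply(alignments, function(a) a$target, "")
  domains <- lapply(alignments, function(a) names(a$eta))
  all_dom <- unique(unlist(domains))
  picked <- integer(0)
  covered <- character(0)
  repeat {
    if (all(all_dom %in% covered)) break
    cand <- setdiff(which(!(centers %in% covered)), picked)
    if (length(cand) == 0L) break
    o <- cand[order(-scores[cand], centers[cand], targets[cand])]
    pick <- o[1L]
    picked <- c(picked, pick)
    covered <- union(covered, domains[[pick]])
  }
  alignments[picked]
}

#' Greedy weighted bipartite hypergraph assignment
#'
#' Each cluster alignment defines a hyperarc from its domain to its image
#' with its score as weight; the payloads of different hyperarcs may
#' conflict on shared source or target nodes. Hyperarcs are processed in
#' decreasing weight (ties by source center); from each payload, every
#' pair whose source and target are both still unassigned is accepted.
#' The exact weighted bipartite hypergraph assignment problem is NP-hard;
#' this greedy rule keeps the best-scored-first spirit of the pipeline and
#' yields an injective map by construction.
#'
#' @param arcs list of hyperarcs: each a list with `source` (center id),
#'   `weight` (positive score) and `pairs` (data frame `source`, `target`
#'   in match order).
#' @return Data frame `source`, `target`: an injective partial map.
#' @export
hypergraph_assign <- function(arcs) {
  empty <- data.frame(source = character(0), target = character(0),
                      stringsAsFactors = FALSE)
  if (length(arcs) == 0L) return(empty)
  w <- vapply(arcs, function(a) a$weight, 0)
  ctr <- vapply(arcs, function(a) a$source, "")
  used_s <- character(0)
  used_t <- character(0)
  out_s <- character(0)
  out_t <- character(0)
  for (a in arcs[order(-w, ctr)]) {
    p <- a$pairs
    for (r in seq_len(nrow(p))) {
      s <- p$source[r]
      t <- p$target[r]
      if (!(s %in% used_s) && !(t %in% used_t)) {
        used_s <- c(used_s, s)
        used_t <- c(used_t, t)
        out_s <- c(out_s, s)
        out_t <- c(out_t, t)
      }
    }
  }
  data.frame(source = out_s, target = out_t, stringsAsFactors = FALSE)
}

#' Extend a local alignment to a global one
#'
#' Iterates the consensus machinery on the still-unaligned nodes: every
#' cluster alignment is restricted to pairs whose source and target are
#' both unaligned, scores are recomputed on the restrictions (only
#' restrictions with non-empty domain keep a positive score), the
#' clustering match and the best-scored subset are rebuilt among those,
#' and the resulting hypergraph assignment is merged into the alignment.
#' The loop runs while some alignment retains a positive updated score;
#' each round fixes at least one new pair, so it terminates after at most
#' `|V|` rounds of the source network (exceeding that cap raises an
#' internal error, as it would indicate non-progress).
#'
#' @param local data frame `source`, `target`, `stage` as produced by the
#'   local stage.
#' @param alignments the full list of computed cluster alignments.
#' @param bits12 cross-network [bit_score_table] (normalized).
#' @param n_source number of nodes of the source network (iteration cap).
#' @return Data frame `source`, `target`, `stage` with the added pairs
#'   tagged `extension-k` for round `k`.
#' @export
extend_to_global <- function(local, alignments, bits12, n_source) {
  bits12 <- normalize_bit_scores(bits12)
  map <- local
  iter <- 0L
  repeat {
    restricted <- lapply(alignments, restrict_alignment,
                         used_s = map$source, used_t = map$target)
    keep <- vapply(restricted, function(a) length(a$eta) > 0L, NA)
    if (!any(keep)) break
    restricted <- restricted[keep]
    maxdom <- max(vapply(restricted, function(a) length(a$eta), 0L))
    scores <- vapply(restricted, score_alignment, 0,
                     bits12 = bits12, maxdom = maxdom)
    sel <- match_clusterings(data.frame(
      source = vapply(restricted, function(a) a$source, ""),
      target = vapply(restricted, function(a) a$target, ""),
      score = scores,
      stringsAsFactors = FALSE
    ))
    key <- paste(vapply(restricted, function(a) a$source, ""),
                 vapply(restricted, function(a) a$target, ""), sep = "\r")
    idx <- match(paste(sel$source, sel$target, sep = "\r"), key)
    best <- select_best_scored(restricted[idx], scores[idx])
    arcs <- lapply(best, function(a) {
      list(source = a$source,
           weight = scores[[match(paste(a$source, a$target, sep = "\r"), key)]],
           pairs = a$pairs[, c("source", "target")])
    })
    new_pairs <- hypergraph_assign(arcs)
    if (nrow(new_pairs) == 0L) break
    iter <- iter + 1L
    if (iter > n_source) {
      stop("internal error: alignment extension failed to make progress")
    }
    new_pairs$stage <- paste0("extension-", iter)
    map <- rbind(map, new_pairs)
  }
  map
}

# Restrict a cluster alignment to pairs with both endpoints unaligned.
restrict_alignment <- function(a, used_s, used_t) {
  keep <- !(a$pairs$source %in% used_s) & !(a$pairs$target %in% used_t)
  p <- a$pairs[keep, , drop = FALSE]
  structure(
    list(source = a$source, target = a$target, pairs = p,
         eta = stats::setNames(p$target, p$source)),
    class = "cluster_alignment"
  )
}
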
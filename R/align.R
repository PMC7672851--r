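#' Global alignment of two protein-protein interaction networks
#'
#' Runs the full parameter-free pipeline. The source is always the network
#' with fewer nodes (inputs are swapped internally if needed):
#'
#' 1. build the overlapping clustering of each network from the node
#'    similarity `s` and its third-quartile threshold;
#' 2. align every cluster pair whose centers have a positive cross bit
#'    score, center-outward by iterated minimum-cost assignment;
#' 3. score the cluster alignments and match the two clusterings by
#'    maximum-weight bipartite matching;
#' 4. select the best-scored subset and merge it into a consistent local
#'    alignment through the greedy hypergraph assignment;
#' 5. iteratively extend the local alignment to a global one over the
#'    still-unaligned nodes.
#'
#' @param net1,net2 [ppin] objects.
#' @param bits1,bits2 within-network [bit_score_table]s for `net1` and
#'   `net2` (raw tables are normalized per table).
#' @param bits12 cross-network [bit_score_table].
#' @return An object of class `ppin_alignment`: list with
#'   `global` and `local` (data frames `source`, `target`, `stage`),
#'   `source_name`/`target_name`, `swapped` (whether the inputs were
#'   reoriented), and `summary` with the pair similarity summary: the edge
#'   correctness of the global alignment and the mean cross bit score over
#'   matched pairs.
#' @examples
#' sp <- generate_pair(20, 20, edge_density = 0.2, seed = 7)
#' al <- ppin_align(sp$net1, sp$net2, sp$bits11, sp$bits22, sp$bits12)
#' head(al$global)
#' al$summary
#' @export
ppin_align <- function(net1, net2, bits1, bits2, bits12) {
  stopifnot(inherits(net1, "ppin"), inherits(net2, "ppin"))
  swapped <- length(ppin_nodes(net1)) > length(ppin_nodes(net2))
  if (swapped) {
    tmp <- net1; net1 <- net2; net2 <- tmp
    tmp <- bits1; bits1 <- bits2; bits2 <- tmp
  }
  bits12 <- normalize_bit_scores(bits12)
  nodes1 <- ppin_nodes(net1)
  nodes2 <- ppin_nodes(net2)

  sim1 <- similarity_matrix(net1, bits1)
  sim2 <- similarity_matrix(net2, bits2)
  clus1 <- build_clustering(net1, sim1)
  clus2 <- build_clustering(net2, sim2)

  ctx <- list(
    deg1 = ppin_degree(net1), deg2 = ppin_degree(net2),
    adj1 = ppin_adjacency(net1), adj2 = ppin_adjacency(net2),
    B = bit_score_dense(bits12, nodes1, nodes2)
  )

  # cluster pairs with positive cross score between their centers
  pos <- which(ctx$B > 0, arr.ind = TRUE)
  empty_map <- data.frame(source = character(0), target = character(0),
                          stage = character(0), stringsAsFactors = FALSE)
  result <- function(global, local, alignments) {
    summary <- list(
      n_matched = nrow(global),
      edge_correctness = if (nrow(global) > 0L &&
                             igraph::ecount(net1$graph) > 0L &&
                             igraph::ecount(net2$graph) > 0L) {
        edge_correctness(global, net1, net2)
      } else {
        NA_real_
      },
      mean_bit_score = if (nrow(global) > 0L) {
        mean(ctx$B[cbind(global$source, global$target)])
      } else {
        NA_real_
      }
    )
    structure(
      list(global = global, local = local,
           source_name = net1$name, target_name = net2$name,
           swapped = swapped, n_cluster_alignments = length(alignments),
           summary = summary),
      class = "ppin_alignment"
    )
  }
  if (nrow(pos) == 0L) {
    warning("no positive cross-network bit score: empty alignment")
    return(result(empty_map, empty_map, list()))
  }
  pos <- pos[order(nodes1[pos[, 1L]], nodes2[pos[, 2L]]), , drop = FALSE]

  alignments <- vector("list", nrow(pos))
  for (r in seq_len(nrow(pos))) {
    u <- nodes1[pos[r, 1L]]
    u2 <- nodes2[pos[r, 2L]]
    alignments[[r]] <- align_cluster_pair_ctx(ctx, u, u2,
                                              clus1[[u]], clus2[[u2]])
  }
  alignments <- alignments[!vapply(alignments, is.null, NA)]

  maxdom <- max(vapply(alignments, function(a) length(a$eta), 0L))
  scores <- vapply(alignments, score_alignment, 0,
                   bits12 = bits12, maxdom = maxdom)
  sel <- match_clusterings(data.frame(
    source = vapply(alignments, function(a) a$source, ""),
    target = vapply(alignments, function(a) a$target, ""),
    score = scores,
    stringsAsFactors = FALSE
  ))
  key <- paste(vapply(alignments, function(a) a$source, ""),
               vapply(alignments, function(a) a$target, ""), sep = "\r")
  idx <- match(paste(sel$source, sel$target, sep = "\r"), key)
  best <- select_best_scored(alignments[idx], scores[idx])
  arcs <- lapply(best, function(a) {
    list(source = a$source,
         weight = scores[[match(paste(a$source, a$target, sep = "\r"), key)]],
         pairs = a$pairs[, c("source", "target")])
  })
  local <- hypergraph_assign(arcs)
  if (nrow(local) > 0L) local$stage <- "local" else local$stage <- character(0)

  global <- extend_to_global(local, alignments, bits12, length(nodes1))
  result(global, local, alignments)
}

#' @export
print.ppin_alignment <- function(x, ...) {
  cat(sprintf("PPIN alignment %s -> %s: %d pairs (%d local)\n",
              x$source_name, x$target_name,
              nrow(x$global), nrow(x$local)))
  if (!is.null(x$summary$edge_correctness) &&
      !is.na(x$summary$edge_correctness)) {
    cat(sprintf("  edge correctness %.4f, mean matched bit score %.4f\n",
                x$summary$edge_correctness, x$summary$mean_bit_score))
  }
  invisible(x)
}

#' Extract the alignment as a named vector
#' @param x a `ppin_alignment` or an alignment data frame.
#' @return Named character vector: source protein -> target protein.
#' @export
alignment_map <- function(x) {
  if (inherits(x, "ppin_alignment")) x <- x$global
  stats::setNames(x$target, x$source)
}

#' Write an alignment as TSV
#'
#' Columns `source`, `target`, `stage` with a header line; the stage tag is
#' `local` for pairs fixed by the local stage and `extension-k` for pairs
#' added in extension round `k`. Re-reading with [read_alignment()]
#' reproduces the map exactly.
#'
#' @param x a `ppin_alignment` or an alignment data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  if (inherits(x, "ppin_alignment")) x <- x$global
  stopifnot(all(c("source", "target", "stage") %in% names(x)))
  utils::write.table(x[, c("source", "target", "stage")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  stopifnot(all(c("source", "target", "stage") %in% names(d)))
  d
}
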
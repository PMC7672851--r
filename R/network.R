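#' Protein-protein interaction network
#'
#' Builds an undirected simple graph of proteins. Self-loops are stripped and
#' duplicate edges collapsed, which is the convention for interaction data:
#' a reported self-interaction carries no information for alignment, and the
#' hop-distance and degree statistics used downstream assume a simple graph.
#' Node order is lexicographic so that all derived quantities are
#' deterministic regardless of the order edges were listed in.
#'
#' @param edges two-column character matrix or data frame, one interaction
#'   per row. Extra columns are ignored.
#' @param name label used in printing.
#' @param nodes optional character vector of node identifiers; the final node
#'   set is the union of `nodes` and all edge endpoints. Allows isolated
#'   proteins to be kept.
#' @return An object of class `ppin`: a list with the `igraph` graph, the
#'   sorted node identifiers, and the counts of removed loops/duplicates.
#' @examples
#' net <- ppin(rbind(c("a", "b"), c("b", "a"), c("c", "c")))
#' ppin_nodes(net)   # "a" "b" "c"
#' ppin_edges(net)   # single edge a-b
#' @export
ppin <- function(edges, name = "ppin", nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) < 2L) {
    stop("'edges' must have at least two columns")
  }
  u <- as.character(edges[, 1L])
  v <- as.character(edges[, 2L])
  loops <- u == v
  a <- pmin(u[!loops], v[!loops])
  b <- pmax(u[!loops], v[!loops])
  dup <- duplicated(pair_key(a, b))
  a <- a[dup == FALSE]
  b <- b[dup == FALSE]
  all_nodes <- sort(unique(c(as.character(nodes), u, v)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  structure(
    list(
      name = name,
      graph = g,
      nodes = all_nodes,
      loops_removed = sum(loops),
      duplicates_removed = sum(dup)
    ),
    class = "ppin"
  )
}

#' @export
print.ppin <- function(x, ...) {
  cat(sprintf(
    "PPIN '%s': %d proteins, %d interactions (%d loops, %d duplicates stripped)\n",
    x$name, length(x$nodes), igraph::ecount(x$graph),
    x$loops_removed, x$duplicates_removed
  ))
  invisible(x)
}

#' Read a PPIN from a tab- or whitespace-separated edge list
#'
#' One interaction per line, first two fields are protein identifiers, extra
#' fields are ignored. Lines starting with `#` and blank lines are skipped.
#' Self-loops and duplicate edges are removed on load.
#'
#' @param path path to the edge-list file.
#' @param name network label; defaults to the file name.
#' @return A [ppin] object.
#' @export
read_ppin <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty network: no edges in '", path, "'")
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge on line %d of '%s': need two identifiers",
                 idx[bad[1L]], path))
  }
  ppin(cbind(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L)),
       name = name)
}

#' Write a PPIN as a two-column edge list
#'
#' @param x a [ppin] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ppin <- function(x, path) {
  stopifnot(inherits(x, "ppin"))
  e <- ppin_edges(x)
  utils::write.table(e, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname ppin
#' @param x a `ppin` object.
#' @export
ppin_nodes <- function(x) {
  stopifnot(inherits(x, "ppin"))
  x$nodes
}

#' @rdname ppin
#' @export
ppin_edges <- function(x) {
  stopifnot(inherits(x, "ppin"))
  if (igraph::ecount(x$graph) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  e <- igraph::as_edgelist(x$graph)
  m <- cbind(from = pmin(e[, 1L], e[, 2L]), to = pmax(e[, 1L], e[, 2L]))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Degrees, adjacency, distances and diameter of a PPIN
#'
#' `ppin_degree` returns the named degree vector; `ppin_adjacency` the named
#' list of neighbor sets; `ppin_distances` the matrix of hop distances
#' (`Inf` between different connected components); `ppin_diameter` the
#' largest finite hop distance (0 for an edgeless network).
#'
#' @param x a [ppin] object.
#' @return See description.
#' @export
ppin_degree <- function(x) {
  stopifnot(inherits(x, "ppin"))
  d <- igraph::degree(x$graph)
  d[x$nodes]
}

#' @rdname ppin_degree
#' @export
ppin_adjacency <- function(x) {
  stopifnot(inherits(x, "ppin"))
  adj <- igraph::as_adj_list(x$graph)
  out <- lapply(adj, function(vs) sort(igraph::V(x$graph)$name[vs]))
  names(out) <- igraph::V(x$graph)$name
  out[x$nodes]
}

#' @rdname ppin_degree
#' @export
ppin_distances <- function(x) {
  stopifnot(inherits(x, "ppin"))
  d <- igraph::distances(x$graph, algorithm = "unweighted")
  d[x$nodes, x$nodes, drop = FALSE]
}

#' @rdname ppin_degree
#' @export
ppin_diameter <- function(x) {
  d <- ppin_distances(x)
  finite <- d[is.finite(d)]
  if (length(finite) == 0L) return(0)
  max(finite)
}
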
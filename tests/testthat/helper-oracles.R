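# Independent brute-force oracles used to cross-check the optimization
# routines, plus small fixture builders. These deliberately avoid the code
# paths they verify (no igraph matching calls).

# all permutations of 1..n as a list
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# minimum total cost over all full-cardinality assignments of a matrix
brute_min_cost_total <- function(cost) {
  transposed <- nrow(cost) > ncol(cost)
  if (transposed) cost <- t(cost)
  nr <- nrow(cost)
  nc <- ncol(cost)
  best <- Inf
  for (cols in utils::combn(nc, nr, simplify = FALSE)) {
    for (p in all_perms(nr)) {
      tot <- sum(cost[cbind(seq_len(nr), cols[p])])
      if (tot < best) best <- tot
    }
  }
  best
}

# maximum total weight over all matchings of a bipartite edge list
# (data frame source/target/score), by recursion over sources
brute_max_matching_total <- function(edges) {
  sources <- unique(edges$source)
  recurse <- function(i, used_targets) {
    if (i > length(sources)) return(0)
    s <- sources[i]
    best <- recurse(i + 1L, used_targets)  # leave s unmatched
    rows <- which(edges$source == s & !(edges$target %in% used_targets))
    for (r in rows) {
      best <- max(best, edges$score[r] +
                    recurse(i + 1L, c(used_targets, edges$target[r])))
    }
    best
  }
  recurse(1L, character(0))
}

# maximum total weight over all injections of the smaller side of a
# rectangular similarity matrix into the larger
brute_injection_max <- function(w) {
  transposed <- nrow(w) > ncol(w)
  if (transposed) w <- t(w)
  nr <- nrow(w)
  nc <- ncol(w)
  best <- 0
  for (cols in utils::combn(nc, nr, simplify = FALSE)) {
    for (p in all_perms(nr)) {
      best <- max(best, sum(w[cbind(seq_len(nr), cols[p])]))
    }
  }
  best
}

# plain R breadth-first search hop distances from one node
bfs_hops <- function(adj, start) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[start] <- 0
  frontier <- start
  level <- 0
  while (length(frontier) > 0L) {
    level <- level + 1
    nxt <- setdiff(unique(unlist(adj[frontier])), names(d)[is.finite(d)])
    d[nxt] <- level
    frontier <- nxt
  }
  d
}

# connected random network fixture with a within-network bit-score table
random_net_fixture <- function(n, density = 0.2, seed = 1) {
  sp <- generate_pair(n, n, overlap = 1, edge_density = density, seed = seed)
  list(net = sp$net1, bits = sp$bits11)
}
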
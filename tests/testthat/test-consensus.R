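make_ca2 <- function(u, u2, eta) {
  structure(list(source = u, target = u2,
                 pairs = data.frame(source = names(eta), target = unname(eta),
                                    F = NA_real_, stringsAsFactors = FALSE),
                 eta = eta),
            class = "cluster_alignment")
}

test_that("best-scored selection is greedy over uncovered centers", {
  # one alignment covering the whole candidate domain union: singleton
  a1 <- make_ca2("a", "x", c(a = "x", b = "y", c = "z"))
  a2 <- make_ca2("b", "y", c(b = "y"))
  got <- select_best_scored(list(a1, a2), c(1.8, 1.2))
  expect_length(got, 1L)
  expect_equal(got[[1]]$source, "a")

  # chained domains: all three selected, in decreasing-score order
  c1 <- make_ca2("a", "x", c(a = "x", b = "y"))
  c2 <- make_ca2("c", "z", c(c = "z", d = "w"))
  c3 <- make_ca2("e", "v", c(e = "v"))
  got3 <- select_best_scored(list(c3, c1, c2), c(1.1, 1.9, 1.5))
  expect_equal(vapply(got3, function(a) a$source, ""), c("a", "c", "e"))

  # equal scores with disjoint domains: lexicographic center first
  d1 <- make_ca2("m", "x", c(m = "x"))
  d2 <- make_ca2("k", "y", c(k = "y"))
  got2 <- select_best_scored(list(d1, d2), c(1.5, 1.5))
  expect_equal(vapply(got2, function(a) a$source, ""), c("k", "m"))
})

test_that("hypergraph assignment resolves conflicts by weight", {
  arc <- function(u, w, eta) list(source = u, weight = w,
                                  pairs = data.frame(source = names(eta),
                                                     target = unname(eta)))
  # disjoint arcs merge completely
  got <- hypergraph_assign(list(arc("a", 1.5, c(a = "x", b = "y")),
                                arc("c", 1.2, c(c = "z"))))
  expect_equal(nrow(got), 3L)

  # conflicting source: the heavier arc wins
  got2 <- hypergraph_assign(list(arc("u", 1.5, c(a = "y")),
                                 arc("w", 2.0, c(a = "x"))))
  expect_equal(got2$target[got2$source == "a"], "x")
  expect_equal(nrow(got2), 1L)

  # four conflicted sources: exactly one assignment each, injective result
  got3 <- hypergraph_assign(list(
    arc("u", 2.0, c(a = "w", b = "x", c = "y", d = "z")),
    arc("v", 1.5, c(a = "z", b = "w", c = "x", d = "y"))
  ))
  expect_equal(nrow(got3), 4L)
  expect_false(anyDuplicated(got3$source) > 0)
  expect_false(anyDuplicated(got3$target) > 0)
  expect_equal(got3$target[got3$source == "a"], "w")

  expect_equal(nrow(hypergraph_assign(list())), 0L)
})

test_that("extension is a no-op when the local alignment already covers", {
  a1 <- make_ca2("a", "x", c(a = "x", b = "y"))
  local <- data.frame(source = c("a", "b"), target = c("x", "y"),
                      stage = "local", stringsAsFactors = FALSE)
  b <- bit_score_table("a", "x", 100)
  expect_identical(extend_to_global(local, list(a1), b, 5L), local)
})

test_that("aligning a network with itself recovers the identity", {
  sp <- generate_pair(50, 50, overlap = 1, edge_density = 0.12, seed = 11)
  g <- sp$net1
  ident_bits <- bit_score_table(ppin_nodes(g), ppin_nodes(g),
                                rep(100, length(ppin_nodes(g))))
  al <- ppin_align(g, g, sp$bits11, sp$bits11, ident_bits)
  m <- alignment_map(al)
  expect_equal(unname(m), names(m))
  expect_equal(al$summary$edge_correctness, 1)
})

test_that("planted correspondences are recovered without noise", {
  for (s in c(1, 5, 12)) {
    sp <- generate_pair(50, 50, overlap = 1, edge_density = 0.1, seed = s)
    al <- ppin_align(sp$net1, sp$net2, sp$bits11, sp$bits22, sp$bits12)
    m <- alignment_map(al)
    hits <- sum(m[names(sp$truth)] == sp$truth, na.rm = TRUE)
    expect_gte(hits / length(sp$truth), 0.9)
  }
})

test_that("global alignments are injective and preserve local pairs", {
  for (s in 1:8) {
    sp <- generate_pair(sample(10:25, 1), sample(25:35, 1),
                        overlap = runif(1, 0.3, 1),
                        edge_density = runif(1, 0.08, 0.3),
                        noise = runif(1, 0, 0.6), seed = s)
    al <- ppin_align(sp$net1, sp$net2, sp$bits11, sp$bits22, sp$bits12)
    g <- al$global
    expect_false(anyDuplicated(g$source) > 0)
    expect_false(anyDuplicated(g$target) > 0)
    expect_true(all(g$source %in% ppin_nodes(sp$net1)))
    expect_true(all(g$target %in% ppin_nodes(sp$net2)))
    # local pairs survive extension untouched
    loc <- al$local
    merged <- merge(loc, g, by = "source")
    expect_equal(merged$target.x, merged$target.y)
    expect_true(all(g$stage[seq_len(nrow(loc))] == "local"))
  }
})

test_that("the source is always the smaller network", {
  sp <- generate_pair(12, 20, overlap = 1, edge_density = 0.2, seed = 33)
  al12 <- ppin_align(sp$net1, sp$net2, sp$bits11, sp$bits22, sp$bits12)
  al21 <- ppin_align(sp$net2, sp$net1, sp$bits22, sp$bits11, sp$bits12)
  expect_true(al21$swapped)
  expect_false(al12$swapped)
  expect_identical(al12$global, al21$global)
})

test_that("a pair without positive cross scores yields an empty alignment", {
  sp <- generate_pair(10, 10, overlap = 1, edge_density = 0.25, seed = 44)
  no_cross <- bit_score_table(ppin_nodes(sp$net2)[1], ppin_nodes(sp$net2)[2], 1)
  expect_warning(
    al <- ppin_align(sp$net1, sp$net2, sp$bits11, sp$bits22, no_cross),
    "empty alignment"
  )
  expect_equal(nrow(al$global), 0L)
})
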
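test_that("edge correctness counts preserved interactions", {
  tri <- ppin(rbind(c("x", "y"), c("y", "z"), c("x", "z")))
  path <- ppin(rbind(c("a", "b"), c("b", "c")))
  mu <- c(a = "x", b = "y", c = "z")
  expect_equal(edge_correctness(mu, path, tri), 1)  # 2 of min(2, 3)

  wedge <- ppin(rbind(c("x", "y"), c("x", "z")))    # drop {y,z}
  expect_equal(edge_correctness(mu, path, wedge), 0.5)

  self <- ppin(rbind(c("a", "b"), c("b", "c")))
  expect_equal(edge_correctness(c(a = "a", b = "b", c = "c"), self, self), 1)
  expect_equal(edge_correctness(c(a = "c", b = "a", c = "b"), path, wedge), 0)

  empty <- ppin(NULL, nodes = c("a", "b"))
  expect_error(edge_correctness(mu, empty, tri), "edgeless")
})

test_that("functional similarity is the Jaccard index of term sets", {
  ann <- annotation_table(c("p", "p", "q", "q", "r", "r"),
                          c("a", "b", "a", "b", "c", "d"))
  expect_equal(functional_similarity("p", "q", ann), 1)
  expect_equal(functional_similarity("p", "r", ann), 0)
  ann2 <- annotation_table(c("s", "s"), c("b", "c"))
  expect_equal(functional_similarity("p", "s", ann, ann2), 1 / 3)
  expect_equal(functional_similarity("none1", "none2", ann), 0)
})

test_that("functional coherence averages over the whole source node set", {
  ann1 <- annotation_table(c("a", "b", "b", "c"), c("t1", "t1", "t2", "t3"))
  ann2 <- annotation_table(c("x", "y", "z"), c("t1", "t1", "t9"))
  # FS: a->x 1, b->y 0.5, c->z 0; node d unmapped
  mu <- c(a = "x", b = "y", c = "z")
  expect_equal(functional_coherence(mu, ann1, ann2, n_source = 4), 1.5 / 4)
  expect_equal(functional_coherence(character(0), ann1, ann2, 4), 0)

  ident <- annotation_table(c("a", "b"), c("t1", "t2"))
  expect_equal(functional_coherence(c(a = "a", b = "b"), ident, ident, 2), 1)
})

test_that("maximum attainable coherence solves the assignment exactly", {
  ident <- annotation_table(c("a", "b"), c("t1", "t2"))
  expect_equal(fc_max(ident, ident, c("a", "b"), c("a", "b")), 1)

  disjoint <- annotation_table(c("x", "y"), c("t8", "t9"))
  expect_equal(fc_max(ident, disjoint, c("a", "b"), c("x", "y")), 0)

  set.seed(21)
  pool <- sprintf("t%d", 1:6)
  for (i in 1:20) {
    n1 <- sample(3:5, 1)
    n2 <- sample(3:5, 1)
    p1 <- sprintf("p%d", 1:n1)
    p2 <- sprintf("q%d", 1:n2)
    a1 <- annotation_table(rep(p1, each = 2), sample(pool, 2 * n1, TRUE))
    a2 <- annotation_table(rep(p2, each = 2), sample(pool, 2 * n2, TRUE))
    fs <- outer(p1, p2, Vectorize(function(u, v) {
      functional_similarity(u, v, a1, a2)
    }))
    expect_equal(fc_max(a1, a2, p1, p2),
                 brute_injection_max(fs) / min(n1, n2), tolerance = 1e-9)
  }
})

test_that("complex coherence assigns by plurality and checks labels", {
  cat1 <- complex_catalog(
    c("c1", "c1", "c1", "c2", "c3"),
    c("a", "b", "c", "d", "e"),
    c("growth", "growth", "growth", "repair", "transport")
  )
  cat2 <- complex_catalog(
    c("k1", "k1", "k2", "k2"),
    c("x", "y", "z", "w"),
    c("growth", "growth", "other", "other")
  )
  # c1: two members into k1 (coherent), one into k2; c2 -> k2 incoherent;
  # c3 unmapped -> not assigned
  mu <- c(a = "x", b = "y", c = "z", d = "w")
  got <- complex_coherence(mu, cat1, cat2)
  expect_equal(got$cp, 1L)
  expect_equal(got$ncp, 1L)
  expect_equal(got$not_assigned, 1L)
  expect_equal(got$cfc, 50)

  # all coherent gives CFC 100
  mu2 <- c(a = "x", b = "y")
  expect_equal(complex_coherence(mu2, cat1, cat2)$cfc, 100)

  # no assignable complex: undefined
  expect_error(complex_coherence(c(e = "q"), cat1, cat2), "undefined")
})

test_that("plurality ties resolve to the lexicographically first complex", {
  cat1 <- complex_catalog(c("c1", "c1"), c("a", "b"), c("f", "f"))
  cat2 <- complex_catalog(c("k2", "k1"), c("x", "y"), c("g", "f"))
  got <- complex_coherence(c(a = "x", b = "y"), cat1, cat2)  # 1 vote each
  expect_equal(got$cp, 1L)  # k1 chosen, shares label "f"
})

test_that("CFC and precision arithmetic match their definitions", {
  expect_equal(complex_cfc(1, 1), 50)
  expect_equal(complex_precision(0, 10), 0)
  expect_error(complex_cfc(0, 0), "undefined")
  expect_error(complex_precision(0, 0), "undefined")
})

test_that("essentiality metrics follow the confusion-table formulas", {
  # perfect alignment of essentiality
  mu <- c(a = "x", b = "y", c = "z", d = "w")
  ess1 <- c("a", "b")
  ess2 <- c("x", "y")
  got <- essentiality_metrics(mu, ess1, ess2)
  expect_equal(got$mcc, 1)
  expect_equal(got$uc, 1)
  expect_equal(got$specificity, 1)
  expect_equal(got$precision, 1)
  expect_equal(got$f1, 1)
  expect_equal(got$accuracy, 1)
  expect_equal(got$balanced_accuracy, 1)

  # image essentiality constant: Y carries no information, UC = 0
  got0 <- essentiality_metrics(mu, ess1, character(0))
  expect_equal(got0$uc, 0)

  # hand-built confusion table TP=40 FP=10 TN=35 FN=15
  src <- sprintf("s%03d", 1:100)
  tgt <- sprintf("t%03d", 1:100)
  mu2 <- setNames(tgt, src)
  x <- rep(c(TRUE, FALSE), c(50, 50))
  y <- c(rep(TRUE, 40), rep(FALSE, 10), rep(FALSE, 35), rep(TRUE, 15))
  got2 <- essentiality_metrics(mu2, src[x], tgt[y])
  expect_equal(got2$counts$tp, 40)
  expect_equal(got2$counts$fn, 15)
  expect_equal(got2$mcc, (40 * 35 - 10 * 15) / sqrt(50 * 55 * 45 * 50))
  expect_equal(got2$specificity, 35 / 50)
  expect_equal(got2$precision, 40 / 50)
  expect_equal(got2$f1, 80 / (80 + 10 + 15))
  expect_equal(got2$accuracy, 75 / 100)
  expect_equal(got2$balanced_accuracy, (40 / 50 + 35 / 50) / 2)

  expect_error(essentiality_metrics(mu, c("a", "b", "c", "d"), ess2),
               "essential and non-essential")
})

test_that("coherence never exceeds its attainable maximum", {
  set.seed(31)
  for (i in 1:25) {
    sp <- generate_pair(sample(6:10, 1), sample(10:14, 1),
                        overlap = runif(1, 0.5, 1), edge_density = 0.3,
                        noise = runif(1, 0, 0.5), seed = i)
    al <- ppin_align(sp$net1, sp$net2, sp$bits11, sp$bits22, sp$bits12)
    n1 <- ppin_nodes(sp$net1)
    n2 <- ppin_nodes(sp$net2)
    fc <- functional_coherence(al, sp$ann1, sp$ann2, length(n1))
    fmax <- fc_max(sp$ann1, sp$ann2, n1, n2)
    expect_lte(fc, fmax + 1e-9)
    expect_gte(fc, 0)
    ec <- al$summary$edge_correctness
    expect_true(is.na(ec) || (ec >= 0 && ec <= 1))
  }
})
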
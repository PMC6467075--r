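test_that("edge lists are canonicalized: symmetrized, de-duplicated, no self-loops", {
  edges <- data.frame(from = c("b", "a", "a", "c", "c"),
                      to = c("a", "b", "a", "d", "d"),
                      confidence = c(0.4, 0.9, 0.5, 0.2, 0.7))
  expect_message(net <- interaction_network(edges), "self-loop")
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$edges$from, c("A", "C"))
  # conflicting duplicate confidences resolved by maximum
  expect_equal(net$edges$confidence[net$edges$from == "A"], 0.9)
  expect_equal(net$edges$confidence[net$edges$from == "C"], 0.7)
})

test_that("internal edge counting matches a brute-force scan and ignores order", {
  tri <- interaction_network(data.frame(from = c("A", "B", "C"),
                                        to = c("B", "C", "A")))
  expect_equal(count_internal_edges(tri, c("A", "B", "C")), 3L)
  expect_equal(count_internal_edges(tri, c("A", "X", "Y")), 0L)

  set.seed(51)
  for (i in 1:10) {
    n <- 25
    nodes <- sprintf("N%02d", 1:n)
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    pick <- pairs[runif(nrow(pairs)) < 0.15, , drop = FALSE]
    edges <- data.frame(from = nodes[pick[, 1]], to = nodes[pick[, 2]])
    shuffled <- edges[sample(nrow(edges)), ]
    flip <- sample(c(TRUE, FALSE), nrow(shuffled), replace = TRUE)
    tmp <- shuffled$from[flip]
    shuffled$from[flip] <- shuffled$to[flip]
    shuffled$to[flip] <- tmp
    net1 <- interaction_network(edges)
    net2 <- interaction_network(shuffled)
    gs <- sample(nodes, 8)
    expect_equal(count_internal_edges(net1, gs),
                 oracle_internal_edges(edges, gs))
    expect_equal(count_internal_edges(net2, gs),
                 count_internal_edges(net1, gs))
  }
})

test_that("resampling test matches hand enumeration on a tiny graph", {
  # path graph A-B-C-D plus isolated E
  net <- interaction_network(data.frame(from = c("A", "B", "C"),
                                        to = c("B", "C", "D")))
  net$nodes <- c(net$nodes, "E")
  res <- ppi_resampling_test(net, c("A", "B", "C"), n_resamples = 3, seed = 1)
  expect_equal(res$observed, 2L)
  expect_equal(res$V, 3L)
  expect_equal(length(res$null), 3L)
  r <- sum(res$null >= 2L)
  expect_equal(res$p, (r + 1) / 4)

  # byte-identical null under the same seed
  res2 <- ppi_resampling_test(net, c("A", "B", "C"), n_resamples = 3, seed = 1)
  expect_identical(res$null, res2$null)
  expect_error(ppi_resampling_test(net, c("Z1", "Z2")), "annotated")
})

test_that("a planted dense module is called significant at the attainable minimum", {
  nodes <- sprintf("N%03d", 1:150)
  mod <- nodes[1:20]
  net <- generate_ppi_network(nodes, background_edge_p = 0.02,
                              planted_module = mod,
                              within_module_edge_p = 0.9, seed = 61)
  res <- ppi_resampling_test(net, mod, n_resamples = 500, seed = 62)
  expect_equal(res$p, 1 / 501)
  expect_gt(res$observed, max(res$null))
})

test_that("resampling power grows with module density", {
  nodes <- sprintf("N%03d", 1:120)
  mod <- nodes[1:15]
  ps <- vapply(c(0.1, 0.35, 0.8), function(wp) {
    net <- generate_ppi_network(nodes, background_edge_p = 0.05,
                                planted_module = mod,
                                within_module_edge_p = wp, seed = 71)
    ppi_resampling_test(net, mod, n_resamples = 300, seed = 72)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_lt(ps[3], 0.05)
})

test_that("drug-target crosstalk applies the strict confidence cutoff", {
  net <- interaction_network(data.frame(
    from = c("IL12RB2", "LTBR", "GENE1", "GENE2"),
    to = c("IL12B", "TNF", "TNF", "GENE3"),
    confidence = c(0.6, 0.4, 0.35, 0.9)))
  ct <- drug_target_crosstalk(net, c("IL12RB2", "LTBR", "GENE1"),
                              c("IL12B", "TNF", "ITGA4"))
  expect_equal(nrow(ct), 2L)
  expect_setequal(ct$query, c("IL12RB2", "LTBR"))
  # GENE1-TNF at exactly 0.35 excluded by the strict rule
  expect_false("GENE1" %in% ct$query)
  expect_equal(attr(ct, "overlap"), character(0))

  none <- drug_target_crosstalk(net, "GENE2", "ITGA4")
  expect_equal(nrow(none), 0L)
  net2 <- interaction_network(data.frame(from = "A", to = "B"))
  expect_error(drug_target_crosstalk(net2, "A", "B"), "confidence")
})

test_that("gene-set enrichment matches the hypergeometric oracle on a toy universe", {
  bg <- sprintf("G%02d", 1:10)
  sets <- list(s1 = bg[1:4], s2 = bg[5:8])
  enr <- gene_set_enrichment(bg[1:4], sets, bg)
  expect_equal(enr$set[1], "s1")
  expect_equal(enr$p[enr$set == "s1"], stats::dhyper(4, 4, 6, 4),
               tolerance = 1e-12)
  expect_equal(enr$p[enr$set == "s2"],
               stats::phyper(-1, 4, 6, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(gene_set_enrichment("ZZ", sets, bg), "no overlap")
})
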
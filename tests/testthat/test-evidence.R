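test_that("probe collapse keeps each gene's most significant probe", {
  probes <- data.frame(probe = c("cg1", "cg2", "cg3", "cg4"),
                       p = c(0.5, 0.01, 0.2, 0.9))
  map <- data.frame(probe = c("cg1", "cg2", "cg3", "cg4"),
                    gene = c("g", "g", "g", "h"))
  out <- collapse_probes(probes, map)
  expect_equal(out$p[out$gene == "G"], 0.01)
  expect_equal(out$p[out$gene == "H"], 0.9)  # single probe passes through

  set.seed(21)
  for (i in 1:20) {
    np <- sample(20:60, 1)
    probes <- data.frame(probe = sprintf("cg%03d", 1:np), p = runif(np))
    map <- data.frame(probe = probes$probe,
                      gene = sample(sprintf("G%02d", 1:10), np, replace = TRUE))
    out <- collapse_probes(probes, map)
    oracle <- tapply(probes$p, toupper(map$gene), min)
    expect_equal(out$gene, sort(names(oracle)))
    expect_equal(out$p, as.numeric(oracle[out$gene]))
  }
})

test_that("probe collapse drops unmapped probes and errors on empty overlap", {
  probes <- data.frame(probe = c("cg1", "cg2"), p = c(0.1, 0.2))
  map <- data.frame(probe = "cg1", gene = "A")
  expect_message(out <- collapse_probes(probes, map), "1 unmapped")
  expect_equal(nrow(out), 1L)
  expect_error(
    suppressMessages(collapse_probes(probes, data.frame(probe = "x", gene = "A"))),
    "no probe")
})

test_that("dimension labelling applies strict FDR and fold-change thresholds", {
  tab <- evidence_table(c("a", "b", "c"), p = c(0.2, 0.3, 0.4),
                        adj_p = c(0.01, 0.05, 0.2), dimension = "gwas")
  lab <- label_dimension(tab, threshold_rule(fdr = 0.05))
  expect_equal(unname(lab), c(1L, 0L, 0L))  # adj_p exactly 0.05 excluded

  deg <- evidence_table(c("a", "b"), p = c(0.001, 0.001),
                        adj_p = c(0.01, 0.01), log2fc = c(0.5, 0.6),
                        dimension = "expression")
  lab <- label_dimension(deg, threshold_rule(0.05, abs_log2fc = 0.58))
  expect_equal(unname(lab), c(0L, 1L))  # |log2FC| = 0.5 fails '> 0.58'

  expect_error(label_dimension(tab, threshold_rule(0.05, abs_log2fc = 0.58)),
               "fold-change")
})

test_that("labelling computes BH per table when adjusted p is absent", {
  tab <- evidence_table(c("a", "b", "c", "d"), p = c(0.005, 0.5, 0.9, 0.02),
                        dimension = "gwas")
  lab <- label_dimension(tab, threshold_rule(0.05))
  expect_equal(lab, stats::setNames(as.integer(bh_adjust(tab$p) < 0.05),
                                    tab$gene))
  # idempotent and order-independent over genes
  perm <- sample(nrow(tab))
  tab2 <- evidence_table(tab$gene[perm], tab$p[perm], dimension = "gwas")
  lab2 <- label_dimension(tab2, threshold_rule(0.05))
  expect_equal(lab2[names(lab)], lab)
})

test_that("duplicate gene records collapse to the minimum raw p with a warning", {
  expect_warning(
    tab <- evidence_table(c("a", "A", "b"), p = c(0.5, 0.01, 0.2)),
    "duplicate")
  expect_equal(tab$p[tab$gene == "A"], 0.01)
  expect_equal(nrow(tab), 2L)
})

test_that("tissue merging is the element-wise union", {
  g <- c("A", "B", "C")
  wb <- stats::setNames(c(1L, 0L, 0L), g)
  sp <- stats::setNames(c(0L, 0L, 1L), g)
  expect_equal(merge_tissue_dimensions(list(wb, sp)),
               stats::setNames(c(1L, 0L, 1L), g))
  expect_error(merge_tissue_dimensions(list(wb, sp[c(2, 1, 3)])), "universe")

  set.seed(9)
  for (i in 1:20) {
    vs <- lapply(1:3, function(k) stats::setNames(rbinom(8, 1, 0.4),
                                                  sprintf("G%d", 1:8)))
    merged <- merge_tissue_dimensions(vs)
    expect_equal(unname(merged),
                 as.integer(vs[[1]] | vs[[2]] | vs[[3]]))
  }
})

test_that("ES matrix keeps exactly the genes with at least one positive label", {
  labs <- list(d1 = stats::setNames(c(1L, 0L, 0L), c("A", "B", "C")),
               d2 = stats::setNames(c(0L, 0L, 1L), c("A", "B", "C")))
  es <- build_es_matrix(labs)
  expect_equal(rownames(es), c("A", "C"))  # all-zero row B excluded
  expect_error(build_es_matrix(list(d1 = stats::setNames(0L, "A"),
                                    d2 = stats::setNames(0L, "A"))),
               "positive")

  set.seed(13)
  for (i in 1:20) {
    g <- sprintf("G%02d", 1:15)
    labs <- lapply(1:4, function(k) stats::setNames(rbinom(15, 1, 0.3), g))
    names(labs) <- sprintf("d%d", 1:4)
    es <- build_es_matrix(labs)
    keep <- g[Reduce(`+`, labs) >= 1]
    expect_setequal(rownames(es), keep)
    # universe invariant under dimension reordering
    es2 <- build_es_matrix(rev(labs))
    expect_equal(rownames(es2), rownames(es))
    expect_equal(unclass(es2)[, colnames(es)], unclass(es)[, colnames(es)],
                 ignore_attr = TRUE)
    # per-dimension positives equal the record-by-record count
    expect_equal(unname(colSums(unclass(es))),
                 vapply(labs, function(l) sum(l[keep]), numeric(1)),
                 ignore_attr = TRUE)
  }
})

test_that("TS matrix is the union of expressed genes and ES genes", {
  labs <- list(d1 = stats::setNames(c(1L, 1L, 0L), c("A", "B", "C")),
               d2 = stats::setNames(c(0L, 1L, 0L), c("A", "B", "C")))
  es <- build_es_matrix(labs)
  expr <- matrix(c(5, 0.2, 9, 0.3,
                   0.1, 0.1, 0.2, 4), ncol = 2,
                 dimnames = list(c("B", "D", "E", "F"), c("t1", "t2")))
  panel <- tissue_panel(expr)

  ts <- build_ts_matrix(es, panel, tissues = "t1", expr_min = 1)
  # expressed in t1: B, E; ES genes A, B retained though A is unexpressed
  expect_setequal(rownames(ts), c("A", "B", "E"))
  expect_equal(sum(unclass(ts)["E", ]), 0L)    # TS-only gene: all-zero row
  expect_equal(unclass(ts)["A", ], unclass(es)["A", ])

  ts_inf <- build_ts_matrix(es, panel, tissues = "t1", expr_min = Inf)
  expect_equal(rownames(ts_inf), rownames(es))
  expect_error(build_ts_matrix(es, panel, tissues = "nope"), "unknown tissue")
})

test_that("pairwise dimension association matches the hypergeometric oracle", {
  g <- sprintf("G%d", 1:8)
  m <- build_es_matrix(list(
    d1 = stats::setNames(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 1L), g),
    d2 = stats::setNames(c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L), g)))
  pw <- pairwise_dimension_association(m)
  a <- 3; b <- 2; cc <- 1; d <- 2
  expect_equal(pw["d1", "d2"], oracle_fisher_two_sided(a, b, cc, d))
  expect_true(is.na(pw["d1", "d1"]))
  expect_equal(pw["d1", "d2"], pw["d2", "d1"])
})

test_that("identical dimensions give an extreme pairwise association", {
  g <- sprintf("G%03d", 1:400)
  lab <- stats::setNames(rep(c(1L, 0L), each = 200), g)
  m <- build_es_matrix(list(d1 = lab, d2 = lab, d3 = stats::setNames(
    c(rep(0L, 200), rep(1L, 200)), g)))
  pw <- pairwise_dimension_association(m)
  expect_lt(pw["d1", "d2"], 1e-50)
})
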
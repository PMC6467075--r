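make_matrix <- function(labels_by_dim, genes) {
  m <- do.call(cbind, labels_by_dim)
  rownames(m) <- genes
  storage.mode(m) <- "integer"
  m
}

test_that("dimension OR is the cross-product of the membership-by-label table", {
  # 40 genes: S of 10 with 8 positives, 30 non-members with 6 positives
  genes <- sprintf("G%02d", 1:40)
  lab <- c(rep(1L, 8), rep(0L, 2), rep(1L, 6), rep(0L, 24))
  m <- make_matrix(list(d1 = lab, d2 = rep(c(1L, 0L), 20)), genes)
  S <- genes[1:10]
  expect_equal(dimension_or(m, S, "d1"), (8 * 24) / (2 * 6))

  # labels independent of membership: OR = 1
  balanced <- make_matrix(list(d1 = rep(c(1L, 0L), 20),
                               d2 = rep(c(1L, 0L), 20)), genes)
  expect_equal(dimension_or(balanced, genes[c(1, 2, 3, 4)], "d1"), 1)

  # all positives inside S, none outside: haldane keeps it finite
  lab2 <- c(rep(1L, 5), rep(0L, 35))
  m2 <- make_matrix(list(d1 = lab2, d2 = rep(c(1L, 0L), 20)), genes)
  or <- dimension_or(m2, genes[1:5], "d1")
  expect_equal(or, (5.5 * 35.5) / (0.5 * 0.5))
  expect_equal(dimension_or(m2, genes[1:5], "d1", zero_cell = "none"), Inf)
})

test_that("combined OR equals the mean minus the population SD of dimension ORs", {
  genes <- sprintf("G%02d", 1:12)
  set.seed(31)
  # identical dimensions: equal ORs, zero penalty, cOR = mu
  col <- c(rep(1L, 4), rep(0L, 2), rep(1L, 2), rep(0L, 4))
  m <- make_matrix(list(d1 = col, d2 = col), genes)
  p <- combined_or(m, genes[1:6])
  expect_equal(p$cor, p$mu)
  expect_equal(p$penalty, 0)

  # hand case engineered to ORs (2, 4): mu 3, penalty 1, cOR 2
  m <- make_matrix(list(d1 = c(1L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L),
                        d2 = c(1L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L)),
                   genes)
  p <- combined_or(m, genes[1:6])
  expect_equal(unname(p$or), c(2, 4))
  expect_equal(p$mu, 3)
  expect_equal(p$penalty, 1)
  expect_equal(p$cor, 2)

  for (i in 1:50) {
    m <- random_small_matrix(12, 3)
    S <- sample(rownames(m), 4)
    p <- combined_or(m, S)
    expect_equal(p$cor, oracle_cor(m, S), tolerance = 1e-12)
    expect_lte(p$cor, p$mu)
    expect_gte(p$penalty, 0)
  }
})

test_that("hill climbing finds a dominant optimum from any start and is deterministic", {
  genes <- sprintf("G%02d", 1:20)
  # exactly 5 genes carry every positive label in both dimensions
  lab <- c(rep(1L, 5), rep(0L, 15))
  m <- make_matrix(list(d1 = lab, d2 = lab), genes)
  for (s in c(1, 7, 99)) {
    run <- megaor_optimize(m, n = 5, seed = s)
    expect_equal(run$genes, genes[1:5])
    expect_true(run$converged)
  }

  set.seed(17)
  m <- random_small_matrix(14, 3)
  r1 <- megaor_optimize(m, n = 5, seed = 42)
  r2 <- megaor_optimize(m, n = 5, seed = 42)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$genes, r2$genes)
  expect_true(all(diff(r1$trace) > 0))
  expect_gte(r1$profile$cor, r1$trace[1])
})

test_that("multi-restart optimization attains the exhaustive maximum on small instances", {
  set.seed(23)
  hits <- 0
  for (i in 1:20) {
    m <- random_small_matrix(10, 3)
    combos <- utils::combn(rownames(m), 4, simplify = FALSE)
    best <- max(vapply(combos, function(s) oracle_cor(m, s), numeric(1)))
    fit <- megaor(m, n = 4, restarts = 25, seed = i)
    hits <- hits + (fit$best$profile$cor >= best - 1e-9)
  }
  expect_gte(hits, 19)
})

test_that("consensus applies the strict more-than-half rule and counts correctly", {
  mk_run <- function(genes, seed = 1) {
    structure(list(genes = sort(genes),
                   profile = list(or = c(d1 = 2, d2 = 2), mu = 2,
                                  penalty = 0, cor = 2, d = 2L),
                   trace = 1, converged = TRUE, iterations = 0L,
                   seed = seed, n = length(genes)),
              class = "megaor_run")
  }
  runs <- c(lapply(1:50, function(i) mk_run(c("A", "B"))),
            lapply(1:50, function(i) mk_run(c("A", "C"))))
  cons <- consensus_genes(runs)
  expect_equal(cons$consensus, "A")           # B and C at exactly 0.5: excluded
  expect_equal(unname(cons$frequency[c("B", "C")]), c(0.5, 0.5))
  expect_equal(unname(cons$frequency["A"]), 1)

  same <- lapply(1:5, function(i) mk_run(c("X", "Y", "Z")))
  cons2 <- consensus_genes(same)
  expect_equal(cons2$consensus, c("X", "Y", "Z"))

  expect_error(consensus_genes(c(runs, list(mk_run(c("A", "B", "C"))))),
               "heterogeneous")
})

test_that("size grid reduces to a single optimization for one size and one restart", {
  set.seed(29)
  m <- random_small_matrix(14, 3)
  g <- megaor_grid(m, sizes = 5, restarts = 1, seed = 3)
  run <- megaor_optimize(m, n = 5, seed = 3)
  expect_equal(g$fits[["5"]]$best$genes, run$genes)
  expect_equal(g$stable_consensus, run$genes)
  expect_equal(g$stable_size, 5)

  g2 <- megaor_grid(m, sizes = c(4, 6), restarts = 5, seed = 3)
  g3 <- megaor_grid(m, sizes = c(4, 6), restarts = 5, seed = 3)
  expect_identical(g2$fits[["4"]]$consensus$frequency,
                   g3$fits[["4"]]$consensus$frequency)
  expect_identical(g2$stable_consensus, g3$stable_consensus)
})

test_that("consensus is invariant to gene order and run order", {
  set.seed(37)
  m <- random_small_matrix(14, 3)
  fit <- megaor(m, n = 5, restarts = 8, seed = 2)
  cons_rev <- consensus_genes(rev(fit$runs))
  expect_equal(cons_rev$consensus, fit$consensus$consensus)
  # gene-order permutation changes nothing about the attainable optimum
  perm <- sample(nrow(m))
  fit_perm <- megaor(m[perm, ], n = 5, restarts = 8, seed = 2)
  expect_equal(fit_perm$best$profile$cor, fit$best$profile$cor,
               tolerance = 1e-12)
  expect_true(all(fit_perm$consensus$consensus %in% rownames(m)))
})
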
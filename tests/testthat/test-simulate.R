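test_that("study generation is deterministic under a fixed seed", {
  cfg <- simulation_config(n_genes = 120, n_planted = 20, rng_seed = 7)
  s1 <- generate_evidence_study(cfg)
  s2 <- generate_evidence_study(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_evidence_study(simulation_config(n_genes = 120, n_planted = 20,
                                                  rng_seed = 8))
  expect_false(identical(s1$tables, s3$tables))
})

test_that("degenerate rates with a point-mass signal p recover the planted set exactly", {
  cfg <- simulation_config(n_genes = 150, n_planted = 25,
                           planted_hit_rate = 1, background_hit_rate = 0,
                           signal_p_shape = 1e-9, rng_seed = 5)
  study <- generate_evidence_study(cfg)
  rule <- threshold_rule(fdr = 1e-6)
  planted <- study$truth$planted_genes
  for (nm in names(study$tables)) {
    tab <- study$tables[[nm]]
    if (is.list(tab) && !inherits(tab, "evidence_table")) {
      tab <- collapse_probes(tab$probes, tab$probe_map, dimension = nm)
      lab <- label_dimension(tab, rule)
    } else if (!is.null(tab$tissue)) {
      lab <- merge_tissue_dimensions(lapply(split_tissues(tab),
                                            label_dimension, rule = rule))
    } else {
      lab <- label_dimension(tab, rule)
    }
    expect_setequal(names(lab)[lab == 1L], planted)
  }
})

test_that("per-dimension signal counts follow the binomial oracle", {
  sim <- simulate_binary_matrix(n_genes = 2000, n_planted = 200,
                                n_dimensions = 5, planted_hit_rate = 0.6,
                                background_hit_rate = 0.05, seed = 11)
  ind <- sim$truth$indicator
  planted <- sim$truth$planted_genes
  mean_hit <- 200 * 0.6
  sd_hit <- sqrt(200 * 0.6 * 0.4)
  for (j in 1:5) {
    hits <- sum(ind[planted, j])
    expect_gt(hits, mean_hit - 3 * sd_hit)
    expect_lt(hits, mean_hit + 3 * sd_hit)
    bg_hits <- sum(ind[setdiff(rownames(ind), planted), j])
    expect_gt(bg_hits, 1800 * 0.05 - 3 * sqrt(1800 * 0.05 * 0.95))
    expect_lt(bg_hits, 1800 * 0.05 + 3 * sqrt(1800 * 0.05 * 0.95))
  }
  # ES restriction keeps exactly the genes with evidence
  expect_setequal(rownames(sim$matrix),
                  rownames(ind)[rowSums(ind) > 0])
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(planted_hit_rate = 0.05,
                                 background_hit_rate = 0.6),
               "background_hit_rate")
  expect_error(simulation_config(n_genes = 10, n_planted = 10), "smaller")
  expect_error(simulate_binary_matrix(planted_hit_rate = 0.2,
                                      background_hit_rate = 0.2),
               "background_hit_rate")
})

test_that("tissue panel generation plants specificity where asked", {
  genes <- sprintf("G%05d", 1:300)
  planted <- genes[1:40]
  panel <- generate_tissue_panel(genes, tissues = 10, frac_specific = 0.05,
                                 planted_genes = planted,
                                 planted_tissues = "tissue01", seed = 3)
  truth <- attr(panel, "truth")
  expect_true(all(truth$planted_specific %in% planted))
  expect_gte(length(truth$planted_specific), 0.5 * length(planted))

  scores <- tissue_specificity_scores(panel)
  sets <- define_tissue_specific_sets(scores, 0.15)
  expect_gt(length(intersect(sets[["tissue01"]], truth$planted_specific)),
            0.8 * length(truth$planted_specific))

  panel2 <- generate_tissue_panel(genes, tissues = 10, frac_specific = 0.05,
                                  planted_genes = planted,
                                  planted_tissues = "tissue01", seed = 3)
  expect_identical(panel$expr, panel2$expr)
  expect_error(generate_tissue_panel(genes, 5, frac_specific = 1.5),
               "frac_specific")
  expect_error(generate_tissue_panel(genes, 5, planted_tissues = "zz"),
               "planted_tissues")
})

test_that("synthetic PPI network has the requested edge structure", {
  nodes <- sprintf("N%03d", 1:30)
  mod <- nodes[1:3]
  net <- generate_ppi_network(nodes, background_edge_p = 0,
                              planted_module = mod,
                              within_module_edge_p = 1, seed = 2)
  expect_equal(count_internal_edges(net, mod), 3L)  # complete triangle
  expect_equal(nrow(net$edges), 3L)                 # no background edges
  expect_true(all(net$edges$confidence >= 0 & net$edges$confidence <= 1))
  expect_equal(net$nodes, sort(nodes))              # isolated nodes retained

  expect_error(generate_ppi_network(nodes, background_edge_p = 0.5,
                                    planted_module = mod,
                                    within_module_edge_p = 0.2),
               "within_module")

  # expected internal edges of a random set match p * k(k-1)/2
  set.seed(4)
  net2 <- generate_ppi_network(sprintf("N%03d", 1:200),
                               background_edge_p = 0.05, seed = 9)
  k <- 40
  counts <- replicate(200, count_internal_edges(net2, sample(net2$nodes, k)))
  expected <- 0.05 * k * (k - 1) / 2
  expect_lt(abs(mean(counts) - expected), 4 * sd(counts) / sqrt(200) + 2)
})

test_that("written studies round-trip through the readers", {
  cfg <- simulation_config(n_genes = 80, n_planted = 15, rng_seed = 13)
  study <- generate_evidence_study(cfg)
  panel <- generate_tissue_panel(study$truth$genes, tissues = 5, seed = 13)
  net <- generate_ppi_network(study$truth$genes, background_edge_p = 0.02,
                              seed = 13)
  dir <- tempfile("study")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- write_study(study, dir, panel = panel, network = net)
  expect_true(all(file.exists(paths)))

  gw <- read_evidence_table(paths[["gwas"]], "gwas")
  expect_equal(gw$gene, study$tables$gwas$gene)
  expect_equal(gw$p, study$tables$gwas$p, tolerance = 1e-12)
  eq <- read_evidence_table(paths[["eqtl"]], "eqtl")
  expect_equal(eq$tissue, study$tables$eqtl$tissue)
  pr <- read_tsv(paths[["methylation_probes"]])
  expect_equal(pr$p, study$tables$methylation$probes$p, tolerance = 1e-12)

  pan <- read_tissue_panel(paths[["panel"]])
  expect_equal(pan$expr, panel$expr, tolerance = 1e-12)
  net2 <- read_edge_list(paths[["network"]])
  expect_equal(net2$edges$from, net$edges$from)
  expect_equal(net2$edges$confidence, net$edges$confidence, tolerance = 1e-12)

  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(sort(truth$planted_genes), study$truth$planted_genes)
})
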
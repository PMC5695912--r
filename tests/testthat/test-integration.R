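test_that("regulator scores are zero when nothing rewires and relate to
           the differential adjacency algebraically", {
  set.seed(2)
  half <- matrix(rnorm(12 * 10), 12)
  es <- toy_eset(cbind(half, half))
  res <- regulator_diffcoex_scores(es, "g1", n_perm = 99, seed = 1)
  expect_true(all(res$score == 0))
  expect_false(any(res$significant))

  es2 <- null_eset(10, 15, seed = 9)
  sc <- regulator_diffcoex_scores(es2, "g2", n_perm = 99, seed = 1)
  fit <- diffcoex(es2, beta = 3, min_module_size = 2)
  # score = |delta c| = 2 * adjacency^(1/beta)
  adj_row <- fit$adjacency["g2", sc$gene]
  expect_equal(sc$score, unname(2 * adj_row^(1 / 3)), tolerance = 1e-10)

  expect_error(regulator_diffcoex_scores(es2, "nope"), "nope")
})

test_that("a planted hub's rewired neighbors attain the minimum
           attainable p", {
  # neighborhood correlation flips sign after training: +0.7 -> -0.7
  cfg <- synthetic_config(n_genes = 120, n_subjects = 50,
                          modules = list(),
                          hub_gene_neighbors_pre = 15,
                          hub_gene_neighbors_post = 15,
                          hub_corr = 0.7, hub_corr_post = -0.7,
                          seed = 17)
  sim <- generate_paired_expression(cfg)
  hub <- sim$truth$hub_gene_id
  sc <- regulator_diffcoex_scores(sim$expression, hub, n_perm = 499,
                                  seed = 3)
  nb <- sim$truth$hub_neighbors_pre
  expect_true(all(sc$p[sc$gene %in% nb] == 1 / 500))
  expect_true(all(sc$significant[sc$gene %in% nb]))
})

test_that("pathway edges appear for the planted neighborhood and stay
           absent under the null", {
  cfg <- synthetic_config(n_genes = 200, n_subjects = 40,
                          modules = list(),
                          hub_gene_neighbors_pre = 20,
                          hub_gene_neighbors_post = 0,
                          hub_corr = 0.7, seed = 23)
  sim <- generate_paired_expression(cfg)
  hub <- sim$truth$hub_gene_id
  col <- generate_gene_sets(sim$truth, n_decoy_sets = 20, set_size = 20,
                            seed = 2)
  sc <- regulator_diffcoex_scores(sim$expression, hub, n_perm = 199,
                                  seed = 3)
  edges <- regulator_pathway_edges(sc, col, sim$expression$gene_ids)
  expect_true("hub_neighborhood" %in% edges$to)
  expect_true(all(edges$evidence == "enrichment"))

  empty <- regulator_pathway_edges(sc, gene_set_collection(list()),
                                   sim$expression$gene_ids)
  expect_equal(nrow(empty), 0)

  # no significant neighborhood -> zero edges with warning
  null_sc <- sc
  null_sc$significant <- FALSE
  expect_warning(e0 <- regulator_pathway_edges(null_sc, col,
                                               sim$expression$gene_ids),
                 "no significant")
  expect_equal(nrow(e0), 0)
})

test_that("phenotype regression recovers a noise-free planted slope
           exactly", {
  cfg <- synthetic_config(
    n_genes = 50, n_subjects = 20, modules = list(),
    hub_gene_neighbors_pre = 5, hub_gene_neighbors_post = 0,
    phenotype_specs = list(list(name = "fitness", n_driver_genes = 1,
                                effect_size = 2, noise_sd = 0)),
    seed = 29)
  sim <- generate_paired_expression(cfg)
  ph <- generate_phenotypes(sim$truth, sim$expression, cfg)
  driver <- sim$truth$phenotype_drivers$fitness$genes
  # noise-free response: lm warns about an essentially perfect fit
  res <- suppressWarnings(
    regulator_phenotype_edges(sim$expression, ph, driver))
  expect_equal(res$fits$slope, 2, tolerance = 1e-9)
  expect_equal(nrow(res$edges), 1)
  expect_identical(res$edges$to, "fitness")
  expect_true(all(res$edges$evidence == "regression"))
})

test_that("OLS slope estimates concentrate around the planted
           coefficient", {
  b <- 1.5; sigma <- 2; n <- 41
  slopes <- vapply(1:50, function(seed) {
    cfg <- synthetic_config(
      n_genes = 10, n_subjects = n, modules = list(),
      hub_gene_neighbors_pre = 2, hub_gene_neighbors_post = 0,
      phenotype_specs = list(list(name = "m", n_driver_genes = 1,
                                  effect_size = b, noise_sd = sigma)),
      seed = 500 + seed)
    sim <- generate_paired_expression(cfg)
    ph <- generate_phenotypes(sim$truth, sim$expression, cfg)
    driver <- sim$truth$phenotype_drivers$m$genes
    regulator_phenotype_edges(sim$expression, ph, driver)$fits$slope
  }, numeric(1))
  # baseline expression has unit variance, so SE(slope) ~ sigma/sqrt(n)
  expect_lt(abs(mean(slopes) - b), 2 * sigma / sqrt(n * 50) * 5)
  expect_lt(abs(mean(slopes) - b), 2 * sigma / (1 * sqrt(n)))
})

test_that("graph assembly merges duplicates, ranks degrees and is
           order-invariant", {
  e <- data.frame(from = c("r1", "r1", "r2"),
                  to = c("P1", "P2", "P1"),
                  from_type = "regulator_gene",
                  to_type = "phenotype",
                  q = c(0.05, 0.02, 0.01), evidence = "regression")
  g <- assemble_graph(e)
  deg <- node_degrees(g)
  expect_equal(deg$degree[deg$node == "r1"], 2)
  expect_equal(deg$degree[deg$node == "P1"], 2)
  expect_equal(deg$degree[deg$node == "r2"], 1)
  expect_equal(sum(deg$degree), 2 * igraph::ecount(g))

  # duplicate edge keeps the best q
  dup <- rbind(e, data.frame(from = "r1", to = "P1",
                             from_type = "regulator_gene",
                             to_type = "phenotype", q = 0.001,
                             evidence = "regression"))
  g2 <- assemble_graph(dup)
  expect_equal(igraph::ecount(g2), 3)
  eid <- igraph::get_edge_ids(g2, c("r1", "P1"))
  expect_equal(igraph::E(g2)$q[eid], 0.001)

  # permuting the edge list changes nothing
  g3 <- assemble_graph(dup[sample(nrow(dup)), ])
  expect_identical(node_degrees(g3), node_degrees(g2))
  expect_equal(igraph::E(g3)$q[igraph::get_edge_ids(g3, c("r1", "P1"))],
               0.001)

  self <- e; self$to[1] <- "r1"
  expect_error(assemble_graph(self), "self-edge")

  empty <- assemble_graph(e[0, ])
  expect_equal(nrow(node_degrees(empty)), 0)
})

test_that("seed networks capture a condition-specific neighborhood", {
  # a gene nearly identical to the seed is found
  set.seed(55)
  ns <- 20
  vals <- matrix(rnorm(10 * 2 * ns), 10)
  vals[2, ] <- vals[1, ] + rnorm(2 * ns, sd = 0.05)
  es <- toy_eset(vals)
  net <- seed_condition_network(es, "g1", "pre",
                                gene_set_collection(list()))
  expect_true("g2" %in% net$significant_genes)
  expect_equal(net$correlations$q[net$correlations$gene == "g2"],
               min(net$correlations$q))

  # post-only hub neighborhood: degree strictly larger post than pre
  cfg <- synthetic_config(n_genes = 150, n_subjects = 40,
                          modules = list(),
                          hub_gene_neighbors_pre = 0,
                          hub_gene_neighbors_post = 20,
                          hub_corr = 0.7, seed = 61)
  sim <- generate_paired_expression(cfg)
  col <- generate_gene_sets(sim$truth, n_decoy_sets = 10, set_size = 20,
                            seed = 4)
  hub <- sim$truth$hub_gene_id
  pre_net <- seed_condition_network(sim$expression, hub, "pre", col)
  post_net <- seed_condition_network(sim$expression, hub, "post", col)
  expect_gt(post_net$degree, pre_net$degree)

  # independent genes: significant fraction near the FDR level
  frac <- vapply(1:10, function(seed) {
    es0 <- null_eset(200, 40, seed = 700 + seed)
    mean(seed_condition_network(es0, "g1", "pre",
                                gene_set_collection(list()),
                                corr_fdr = 0.05)$correlations$significant)
  }, numeric(1))
  expect_lt(mean(frac), 0.05 + 0.03)
})
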
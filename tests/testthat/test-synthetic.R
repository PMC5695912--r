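test_that("generator is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_genes = 100, n_subjects = 10, seed = 42,
                          modules = list(list(size = 10, rewired = TRUE,
                                              within_corr_pre = 0.6,
                                              within_corr_post = 0)),
                          hub_gene_neighbors_pre = 5,
                          hub_gene_neighbors_post = 0,
                          phenotype_specs = list(
                            list(name = "ph", n_driver_genes = 1,
                                 effect_size = 1, noise_sd = 1)))
  a <- generate_paired_expression(cfg)
  b <- generate_paired_expression(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_phenotypes(a$truth, a$expression, cfg),
                   generate_phenotypes(b$truth, b$expression, cfg))
  expect_identical(generate_gene_sets(a$truth, 5, 10, seed = 3),
                   generate_gene_sets(b$truth, 5, 10, seed = 3))
})

test_that("background genes are uncorrelated at the Fisher-z scale", {
  cfg <- synthetic_config(n_genes = 60, n_subjects = 50, modules = list(),
                          hub_gene_neighbors_pre = 0,
                          hub_gene_neighbors_post = 0, seed = 5)
  sim <- generate_paired_expression(cfg)
  r <- pairwise_correlation(sim$expression, "pre")
  off <- abs(r[upper.tri(r)])
  # |r| <= 0.5 for n = 50 in at least 99% of null pairs
  expect_gte(mean(off <= 0.5), 0.99)
})

test_that("within-module correlation converges to the configured target", {
  cfg <- synthetic_config(n_genes = 40, n_subjects = 100,
                          modules = list(list(size = 20, rewired = FALSE,
                                              within_corr_pre = 0.81,
                                              within_corr_post = 0.81)),
                          hub_gene_neighbors_pre = 0,
                          hub_gene_neighbors_post = 0, seed = 8)
  sim <- generate_paired_expression(cfg)
  r <- pairwise_correlation(sim$expression, "pre")
  mod <- names(sim$truth$module_of_gene)[sim$truth$module_of_gene == 1]
  rr <- r[mod, mod]
  expect_lt(abs(mean(rr[upper.tri(rr)]) - 0.81), 0.1)

  # fidelity at larger n, tighter tolerance, both conditions
  cfg2 <- synthetic_config(n_genes = 40, n_subjects = 200,
                           modules = list(list(size = 25, rewired = TRUE,
                                               within_corr_pre = 0.6,
                                               within_corr_post = 0.3)),
                           hub_gene_neighbors_pre = 0,
                           hub_gene_neighbors_post = 0, seed = 9)
  sim2 <- generate_paired_expression(cfg2)
  mod2 <- names(sim2$truth$module_of_gene)[sim2$truth$module_of_gene == 1]
  for (cond in c("pre", "post")) {
    target <- if (cond == "pre") 0.6 else 0.3
    rr <- pairwise_correlation(sim2$expression, cond)[mod2, mod2]
    expect_lt(abs(mean(rr[upper.tri(rr)]) - target), 0.05)
  }
})

test_that("subject-label permutation leaves background correlations
           exchangeable", {
  ks_p <- vapply(1:10, function(seed) {
    sim <- generate_paired_expression(synthetic_config(
      n_genes = 30, n_subjects = 30, modules = list(),
      hub_gene_neighbors_pre = 0, hub_gene_neighbors_post = 0,
      seed = seed))
    es <- sim$expression
    set.seed(seed + 1000)
    flipped <- flip_conditions(es, stats::runif(30) < 0.5)
    z <- function(e) {
      r <- pairwise_correlation(e, "pre")
      atanh(r[upper.tri(r)])
    }
    suppressWarnings(stats::ks.test(z(es), z(flipped))$p.value)
  }, numeric(1))
  expect_gt(min(ks_p), 0.01)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_genes = 10, modules = list(
    list(size = 20, rewired = TRUE, within_corr_pre = 0.5,
         within_corr_post = 0))), "exceed")
  expect_error(synthetic_config(n_subjects = 3), "at least 4")
  expect_error(synthetic_config(modules = list(
    list(size = 5, rewired = TRUE, within_corr_pre = 1.5,
         within_corr_post = 0))), "\\[-1, 1\\]")
})

test_that("phenotypes are the configured linear function of baseline
           expression", {
  cfg <- synthetic_config(
    n_genes = 30, n_subjects = 10,
    modules = list(list(size = 5, rewired = TRUE,
                        within_corr_pre = 0.5, within_corr_post = 0)),
    hub_gene_neighbors_pre = 0, hub_gene_neighbors_post = 0,
    phenotype_specs = list(list(name = "exact", n_driver_genes = 1,
                                effect_size = 2, noise_sd = 0)),
    seed = 12)
  sim <- generate_paired_expression(cfg)
  ph <- generate_phenotypes(sim$truth, sim$expression, cfg)
  driver <- sim$truth$phenotype_drivers$exact$genes
  pre <- condition_matrix(sim$expression, "pre")
  expect_equal(ph$delta[match(colnames(pre), ph$subject)],
               as.numeric(2 * pre[driver, ]), tolerance = 1e-12)

  # unknown driver gene is named in the error
  bad <- sim$truth
  bad$phenotype_drivers$exact$genes <- "ghost"
  expect_error(generate_phenotypes(bad, sim$expression, cfg), "ghost")
})

test_that("null phenotypes give roughly uniform regression p-values", {
  cfg <- synthetic_config(
    n_genes = 200, n_subjects = 41, modules = list(),
    hub_gene_neighbors_pre = 0, hub_gene_neighbors_post = 0,
    phenotype_specs = list(list(name = "null_ph", n_driver_genes = 0,
                                effect_size = 0, noise_sd = 1)),
    seed = 21)
  sim <- generate_paired_expression(cfg)
  ph <- generate_phenotypes(sim$truth, sim$expression, cfg)
  fits <- regulator_phenotype_edges(sim$expression, ph,
                                    sim$expression$gene_ids)$fits
  expect_gt(suppressWarnings(
    stats::ks.test(fits$p, "punif")$p.value), 0.01)
})

test_that("gene-set generation plants modules and draws decoys from
           background", {
  cfg <- synthetic_config(
    n_genes = 300, n_subjects = 10,
    modules = list(list(size = 20, rewired = TRUE,
                        within_corr_pre = 0.5, within_corr_post = 0)),
    hub_gene_neighbors_pre = 0, hub_gene_neighbors_post = 0, seed = 2)
  sim <- generate_paired_expression(cfg)
  planted_only <- generate_gene_sets(sim$truth, n_decoy_sets = 0,
                                     set_size = 10, seed = 1)
  expect_identical(unclass(planted_only)[names(sim$truth$planted_sets)],
                   sim$truth$planted_sets)

  col <- generate_gene_sets(sim$truth, n_decoy_sets = 40, set_size = 25,
                            seed = 7)
  decoys <- col[grepl("^decoy", names(col))]
  # decoys never touch planted module genes ...
  planted <- unlist(sim$truth$planted_sets)
  expect_true(all(vapply(decoys, function(s)
    length(intersect(s, planted)) == 0, logical(1))))
  # ... and their overlap with a fixed background subset matches the
  # hypergeometric mean  m * K / N
  bg <- sim$truth$background_genes
  ref <- bg[seq_len(100)]
  overlaps <- vapply(decoys, function(s)
    length(intersect(s, ref)), numeric(1))
  expected <- 25 * 100 / length(bg)
  expect_lt(abs(mean(overlaps) - expected), 2)

  expect_error(generate_gene_sets(sim$truth, 1,
                                  set_size = length(bg) + 1, seed = 1),
               "exceeds")
})
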
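test_that("pairwise correlation matches a direct covariance-formula oracle", {
  es <- toy_eset(rbind(c(1, 2, 3, 2, 4, 6),
                       c(2, 4, 6, 1, 2, 3)))
  r_pre <- pairwise_correlation(es, "pre")
  expect_equal(r_pre[1, 2], 1)
  es2 <- toy_eset(rbind(c(1, 2, 3, 0, 0, 1),
                        c(-1, -2, -3, 1, 0, 0)))
  expect_equal(pairwise_correlation(es2, "pre")[1, 2], -1)

  set.seed(3)
  m <- matrix(rnorm(4 * 10), 4)
  es3 <- toy_eset(m)
  expect_equal(pairwise_correlation(es3, "pre"),
               naive_pearson(condition_matrix(es3, "pre")),
               tolerance = 1e-10, ignore_attr = TRUE)

  flat <- toy_eset(rbind(c(1, 1, 1, 2, 3, 4), c(1, 2, 3, 4, 5, 7)))
  expect_error(pairwise_correlation(flat, "pre"), "g1")
})

test_that("differential adjacency follows (|delta c|/2)^beta with zero
           diagonal", {
  c1 <- matrix(c(1, 0.8, 0.8, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  c2 <- matrix(c(1, 0, 0, 1), 2, dimnames = dimnames(c1))
  cp_same <- correlation_pair(c1, c1)
  expect_equal(differential_adjacency(cp_same, 6),
               matrix(0, 2, 2, dimnames = dimnames(c1)))
  cp <- correlation_pair(c1, c2)
  expect_equal(differential_adjacency(cp, 2)[1, 2], 0.16)
  c3 <- matrix(c(1, 1, 1, 1), 2, dimnames = dimnames(c1))
  c4 <- matrix(c(1, -1, -1, 1), 2, dimnames = dimnames(c1))
  expect_equal(differential_adjacency(correlation_pair(c3, c4), 1)[1, 2], 1)
  expect_error(differential_adjacency(cp, 0), "positive")
})

test_that("topological overlap equals the triple-loop oracle", {
  full <- matrix(1, 3, 3); diag(full) <- 0
  expect_equal(topological_overlap(full),
               matrix(1, 3, 3))

  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 0.5
  tom <- topological_overlap(iso)
  expect_equal(tom[3, 1], 0)
  expect_equal(tom[3, 2], 0)

  for (seed in 1:50) {
    set.seed(seed)
    a <- matrix(runif(64), 8); a <- (a + t(a)) / 2; diag(a) <- 0
    expect_equal(topological_overlap(a), naive_tom(a),
                 tolerance = 1e-12)
  }
})

test_that("module clustering separates block structure and ignores noise", {
  n <- 40
  tom <- matrix(0, n, n)
  tom[1:20, 1:20] <- 0.9
  tom[21:40, 21:40] <- 0.9
  diag(tom) <- 1
  rownames(tom) <- colnames(tom) <- sprintf("g%02d", 1:n)
  part <- cluster_modules(tom, min_module_size = 10)
  expect_equal(max(part), 2)
  expect_length(unique(part[1:20]), 1)
  expect_length(unique(part[21:40]), 1)
  expect_false(part[1] == part[21])

  zero <- diag(1, n)
  rownames(zero) <- colnames(zero) <- rownames(tom)
  expect_true(all(cluster_modules(zero, min_module_size = 10) == 0))
})

test_that("planted rewired modules are recovered with high ARI", {
  skip_if_not_installed("mclust")
  cfg <- synthetic_config(n_genes = 400, n_subjects = 40, seed = 7,
                          modules = replicate(5, list(
                            size = 25, rewired = TRUE,
                            within_corr_pre = 0.7,
                            within_corr_post = 0), simplify = FALSE),
                          hub_gene_neighbors_pre = 0,
                          hub_gene_neighbors_post = 0)
  sim <- generate_paired_expression(cfg)
  fit <- diffcoex(sim$expression)
  ari <- mclust::adjustedRandIndex(sim$truth$module_of_gene,
                                   as.integer(fit$partition))
  expect_gte(ari, 0.8)
})

test_that("module dispersion matches hand-computed values and is
           symmetric", {
  nm <- c("a", "b", "c", "d")
  c1 <- diag(1, 4); c2 <- diag(1, 4)
  dimnames(c1) <- dimnames(c2) <- list(nm, nm)
  c1["a", "c"] <- c1["c", "a"] <- 0.8
  cp <- correlation_pair(c1, c2)
  expect_equal(module_dispersion(cp, "a", "c"), 0.4)

  c1["a", "d"] <- c1["d", "a"] <- 0.6
  c1["b", "c"] <- c1["c", "b"] <- 0.8
  cp <- correlation_pair(c1, c2)
  # pairs (a,c): 0.4, (a,d): 0.3, (b,c): 0.4, (b,d): 0
  expect_equal(module_dispersion(cp, c("a", "b"), c("c", "d")),
               sqrt((0.16 + 0.09 + 0.16 + 0) / 4))
  expect_equal(module_dispersion(cp, c("a", "b"), c("c", "d")),
               module_dispersion(cp, c("c", "d"), c("a", "b")))
  # two within-module pairs with half-differences 0.3 and 0.4
  c3 <- diag(1, 4); dimnames(c3) <- list(nm, nm)
  c4 <- c3
  c3["a", "b"] <- c3["b", "a"] <- 0.6
  c3["a", "c"] <- c3["c", "a"] <- 0.8
  cp2 <- correlation_pair(c3, c4)
  expect_equal(module_dispersion(cp2, c("a", "b")), sqrt(0.09))
  expect_equal(module_dispersion(cp2, c("a", "b", "c"))^2,
               (0.09 + 0.16 + 0) / 3)
  expect_equal(module_dispersion(correlation_pair(c3, c3),
                                 c("a", "b", "c")), 0)
  expect_error(module_dispersion(cp2, "a"), "at least 2")
})

test_that("identical conditions give p = 1 everywhere and remove all
           pairs", {
  set.seed(4)
  half <- matrix(rnorm(20 * 10), 20)
  es <- toy_eset(cbind(half, half))  # pre == post
  part <- structure(setNames(rep(1L, 20), es$gene_ids),
                    min_module_size = 10, class = "ModulePartition")
  res <- filter_gene_pairs(es, part, n_perm = 99, seed = 1)
  expect_true(all(res$pairs$statistic == 0))
  expect_true(all(res$pairs$p == 1))
  expect_false(any(res$pairs$retained))
  expect_true(all(res$partition == 0))
})

test_that("a strongly rewired pair attains the minimum attainable p and
           is retained", {
  # 5-gene module: 10 tested pairs, so the minimum attainable p of
  # 1/1000 maps to a BH q of at most 0.01 and the pair survives the
  # FDR-1% filter
  es <- planted_pair_eset(5, 50, rho_pre = 0.9, rho_post = -0.9,
                          seed = 6)
  part <- structure(setNames(rep(1L, 5), es$gene_ids),
                    min_module_size = 5, class = "ModulePartition")
  res <- filter_gene_pairs(es, part, n_perm = 999, seed = 2)
  row <- res$pairs[res$pairs$gene_a == "g1" & res$pairs$gene_b == "g2", ]
  expect_equal(row$p, 1 / 1000)
  expect_true(row$retained)
})

test_that("pair-filter p-values are super-uniform under the global null", {
  pooled <- unlist(lapply(1:5, function(seed) {
    es <- null_eset(15, 40, seed = 100 + seed)
    part <- structure(setNames(rep(1L, 15), es$gene_ids),
                      min_module_size = 10, class = "ModulePartition")
    filter_gene_pairs(es, part, n_perm = 199, seed = seed)$pairs$p
  }))
  for (level in c(0.01, 0.05, 0.1))
    expect_lte(mean(pooled <= level), level + 0.05)
})

test_that("a larger planted correlation change never raises the pair's
           p-value", {
  p_at <- vapply(c(0.2, 0.5, 0.8), function(rho) {
    es <- planted_pair_eset(10, 50, rho_pre = rho, rho_post = -rho,
                            seed = 42)
    part <- structure(setNames(rep(1L, 10), es$gene_ids),
                      min_module_size = 5, class = "ModulePartition")
    res <- filter_gene_pairs(es, part, n_perm = 199, seed = 9)
    res$pairs$p[res$pairs$gene_a == "g1" & res$pairs$gene_b == "g2"]
  }, numeric(1))
  expect_true(all(diff(p_at) <= 0))
})

test_that("dispersion significance flags planted co-rewired modules and
           nothing under identical conditions", {
  # identical pre/post: all observed d = 0, no edges
  set.seed(11)
  half <- matrix(rnorm(30 * 12), 30)
  es0 <- toy_eset(cbind(half, half))
  part0 <- structure(setNames(rep(1:3, each = 10), es0$gene_ids),
                     min_module_size = 5, class = "ModulePartition")
  d0 <- dispersion_significance(es0, part0, n_random = 100, seed = 1)
  expect_true(all(d0$d == 0))
  expect_false(any(d0$edge))

  # two modules sharing a latent factor whose sign flips between
  # conditions: their inter-module edge attains the smallest p in table
  cfg <- synthetic_config(
    n_genes = 150, n_subjects = 40,
    modules = replicate(3, list(size = 20, rewired = TRUE,
                                within_corr_pre = 0.7,
                                within_corr_post = 0.7),
                        simplify = FALSE),
    hub_gene_neighbors_pre = 0, hub_gene_neighbors_post = 0,
    coupling = list(a = 1, b = 2, corr_pre = 0.5, corr_post = -0.5),
    seed = 31)
  sim <- generate_paired_expression(cfg)
  truth_part <- structure(
    setNames(sim$truth$module_of_gene, names(sim$truth$module_of_gene)),
    min_module_size = 10, class = "ModulePartition")
  disp <- dispersion_significance(sim$expression, truth_part,
                                  n_random = 300, seed = 5)
  cross12 <- disp[disp$module_a == 1 & disp$module_b == 2, ]
  expect_true(cross12$edge)
  expect_equal(cross12$p, min(disp$p))
})

test_that("module graph carries sizes, edges and attributes", {
  labels <- setNames(rep(1:3, times = c(12, 11, 10)),
                     sprintf("g%02d", 1:33))
  part <- structure(labels, min_module_size = 10,
                    class = "ModulePartition")
  disp <- data.frame(module_a = c(1, 1, 2, 1, 2, 3),
                     module_b = c(2, 3, 3, 1, 2, 3),
                     size_a = 1, size_b = 1,
                     d = c(0.4, 0.1, 0.3, 0.5, 0.5, 0.5),
                     p = 0.001, q = c(0.01, 0.5, 0.05, 0.01, 0.01, 0.01),
                     edge = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  g <- build_module_graph(part, disp)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)  # self-pairs are not loops
  expect_equal(igraph::V(g)$size, c(12, 11, 10))
  expect_equal(sort(igraph::E(g)$d), c(0.3, 0.4))

  none <- disp; none$edge <- FALSE
  g0 <- build_module_graph(part, none)
  expect_equal(igraph::vcount(g0), 3)
  expect_equal(igraph::ecount(g0), 0)
})
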
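# Shared fixture builders.  All fixtures are generated in code; tests that
# need randomness seed it explicitly.

# Tiny paired expression set from an explicit genes x (2 * n_subjects)
# matrix: first half of the columns is "pre", second half "post", both in
# subject order.
toy_eset <- function(values, gene_ids = NULL) {
  ns <- ncol(values) / 2
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(nrow(values)))
  rownames(values) <- gene_ids
  paired_expression_set(
    values,
    subject_ids = rep(sprintf("s%02d", seq_len(ns)), 2),
    condition_labels = rep(c("pre", "post"), each = ns))
}

# Random i.i.d. Gaussian eset: the global null (no rewiring, no signal).
null_eset <- function(n_genes, n_subjects, seed) {
  set.seed(seed)
  toy_eset(matrix(rnorm(n_genes * 2 * n_subjects), n_genes))
}

# Eset in which one gene pair has a controlled correlation in each
# condition (rho_pre, rho_post) and all other genes are background noise.
planted_pair_eset <- function(n_genes, n_subjects, rho_pre, rho_post,
                              seed) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * 2 * n_subjects), n_genes)
  mk <- function(rho, ns) {
    f <- rnorm(ns)
    s <- sign(rho); rho <- abs(rho)
    rbind(sqrt(rho) * f + sqrt(1 - rho) * rnorm(ns),
          s * sqrt(rho) * f + sqrt(1 - rho) * rnorm(ns))
  }
  ns <- n_subjects
  vals[1:2, 1:ns] <- mk(rho_pre, ns)
  vals[1:2, ns + 1:ns] <- mk(rho_post, ns)
  toy_eset(vals)
}

# Brute-force Pearson correlation from the covariance formula.
naive_pearson <- function(m) {
  n <- nrow(m)
  out <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    x <- m[i, ]; y <- m[j, ]
    out[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  out
}

# Triple-loop TOM oracle.
naive_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Brute-force BH step-up from the definition.
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exhaustive hypergeometric upper tail by enumerating overlap outcomes.
naive_hyper_upper <- function(k, set_size, universe, query) {
  probs <- vapply(0:min(set_size, query), function(x)
    choose(set_size, x) * choose(universe - set_size, query - x) /
      choose(universe, query), numeric(1))
  sum(probs[(k + 1):length(probs)])
}

# Dense-grid nearest-neighbor oracle for Voronoi domain areas within a
# rectangle [0, w] x [0, h].
grid_domain_areas <- function(pts, w, h, resolution) {
  gx <- (seq_len(resolution) - 0.5) / resolution * w
  gy <- (seq_len(resolution) - 0.5) / resolution * h
  grid <- cbind(rep(gx, times = resolution),
                rep(gy, each = resolution))
  d2 <- matrix(0, nrow(grid), nrow(pts))
  for (i in seq_len(nrow(pts)))
    d2[, i] <- (grid[, 1] - pts[i, 1])^2 + (grid[, 2] - pts[i, 2])^2
  nearest <- max.col(-d2, ties.method = "first")
  cell <- (w / resolution) * (h / resolution)
  tabulate(nearest, nbins = nrow(pts)) * cell
}

square_region <- function(w = 1, h = w) {
  cbind(c(0, w, w, 0), c(0, 0, h, h))
}
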
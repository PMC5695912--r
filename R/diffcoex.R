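# Differential co-expression network construction.  The pipeline follows
# the DiffCoEx idea within the WGCNA framework: the quantity that is
# networked is not co-expression itself but its CHANGE between the two
# conditions.  Gene pairs whose correlation differs strongly between pre
# and post get a high differential adjacency, topological overlap smooths
# this over shared neighbors, and average-linkage clustering of 1 - TOM
# yields modules of co-rewired genes.  Two permutation filters follow: a
# paired condition-shuffle null on individual gene pairs, and a
# size-matched random-cluster null on the module-module dispersion
# statistic.

#' Pairwise correlation matrix of one condition
#'
#' @param eset a `PairedExpressionSet`.
#' @param condition `"pre"` or `"post"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal, genes in the
#'   order of `eset$gene_ids`.
#' @export
pairwise_correlation <- function(eset, condition = c("pre", "post"),
                                 method = c("pearson", "spearman")) {
  condition <- match.arg(condition)
  method <- match.arg(method)
  m <- condition_matrix(eset, condition)
  if (ncol(m) < 3L) stop("need at least 3 samples per condition")
  v <- apply(m, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(m)[v == 0], collapse = ", "))
  r <- stats::cor(t(m), method = method)
  diag(r) <- 1
  r
}

#' Correlation pair for the two conditions
#'
#' Bundles the pre and post correlation matrices (same gene order) used by
#' the differential-network steps.
#'
#' @param corr_pre,corr_post symmetric correlation matrices in \[-1, 1\]
#'   with unit diagonal and identical gene ordering.
#' @param method correlation method the matrices were computed with.
#' @return object of class `"CorrelationPair"`.
#' @export
correlation_pair <- function(corr_pre, corr_post, method = "pearson") {
  for (m in list(corr_pre, corr_post)) {
    if (max(abs(m - t(m))) > 1e-12) stop("correlation matrix not symmetric")
    if (max(abs(diag(m) - 1)) > 1e-12) stop("diagonal must be 1")
    if (max(abs(m)) > 1 + 1e-12) stop("correlations must lie in [-1, 1]")
  }
  if (!identical(dim(corr_pre), dim(corr_post)))
    stop("pre and post matrices must have identical dimensions")
  if (!identical(rownames(corr_pre), rownames(corr_post)))
    stop("pre and post matrices must share gene ordering")
  structure(list(corr_pre = corr_pre, corr_post = corr_post,
                 method = method),
            class = "CorrelationPair")
}

#' Differential adjacency
#'
#' `a_ij = (|c_pre_ij - c_post_ij| / 2)^beta` with zero diagonal; the
#' division by two maps the maximal correlation change (from +1 to -1)
#' onto adjacency 1, and the soft-threshold exponent `beta` suppresses
#' small, noise-level changes.
#'
#' @param cp a [correlation_pair()].
#' @param beta positive soft-threshold exponent.
#' @return adjacency matrix in \[0, 1\].
#' @export
differential_adjacency <- function(cp, beta = 6) {
  stopifnot(inherits(cp, "CorrelationPair"))
  if (beta <= 0) stop("beta must be positive")
  a <- (abs(cp$corr_pre - cp$corr_post) / 2)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `T_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with connectivity `k_i = sum_u a_iu` and `T_ii = 1`.  Two
#' genes overlap strongly when they share differential neighbors even if
#' their direct differential adjacency is modest.
#'
#' @param adjacency matrix in \[0, 1\] with zero diagonal.
#' @return TOM matrix with entries in \[0, 1\] and unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Module detection on the topological overlap
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`.
#' The tree is cut at a height adapted to the merge-height range of the
#' dendrogram: `h = min + cut_fraction * (max - min)`, so that branches
#' joining in the top `(1 - cut_fraction)` stretch of the tree are
#' separated regardless of the absolute TOM scale (differential TOM
#' values are typically small, pushing all dissimilarities close to 1).
#' A fixed absolute height can be supplied instead via `cut_height`.
#' Clusters smaller than `min_module_size` are left unassigned (label 0);
#' labels are contiguous positive integers ordered by decreasing size.
#' A degenerate tree (all merges at the same height, e.g. an all-zero
#' TOM) yields no modules.
#'
#' @param tom TOM matrix.
#' @param min_module_size smallest cluster reported as a module.
#' @param cut_height optional fixed tree-cut height on the 1 - TOM scale;
#'   overrides `cut_fraction`.
#' @param cut_fraction position of the adaptive cut within the
#'   merge-height range (default 0.99); smaller values split more
#'   aggressively, like a deeper dynamic split.
#' @return a `"ModulePartition"`: named integer vector gene -> label, with
#'   attributes `min_module_size` and `cut_height`.
#' @export
cluster_modules <- function(tom, min_module_size = 10, cut_height = NULL,
                            cut_fraction = 0.99) {
  stopifnot(min_module_size >= 2)
  n <- nrow(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(n))
  if (n < min_module_size) {
    warning("fewer genes than min_module_size: no modules")
    return(module_partition(setNames(integer(n), genes),
                            min_module_size, cut_height))
  }
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  # average linkage is monotone; rounding noise can still leave heights
  # microscopically unsorted, which cutree rejects
  if (is.unsorted(tree$height)) tree$height <- cummax(tree$height)
  h_rng <- range(tree$height)
  if (is.null(cut_height)) {
    if (diff(h_rng) < 1e-12)
      return(module_partition(setNames(integer(n), genes),
                              min_module_size, NA_real_))
    cut_height <- h_rng[1] + cut_fraction * diff(h_rng)
  }
  raw <- stats::cutree(tree, h = cut_height)
  module_partition(relabel_by_size(raw, min_module_size, genes),
                   min_module_size, cut_height)
}

relabel_by_size <- function(raw, min_module_size, genes) {
  tab <- table(raw)
  keep <- names(tab)[tab >= min_module_size]
  keep <- keep[order(-tab[keep], as.integer(keep))]
  labels <- integer(length(raw))
  for (i in seq_along(keep))
    labels[raw == as.integer(keep[i])] <- i
  setNames(labels, genes)
}

module_partition <- function(labels, min_module_size, cut_height = NA) {
  structure(labels, min_module_size = min_module_size,
            cut_height = cut_height, class = "ModulePartition")
}

#' @export
print.ModulePartition <- function(x, ...) {
  k <- max(x)
  cat("ModulePartition:", k, "modules,",
      sum(x > 0), "of", length(x), "genes assigned\n")
  if (k > 0) {
    sizes <- table(x[x > 0])
    cat("module sizes:", paste(sizes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit a differential co-expression network
#'
#' End-to-end construction: per-condition correlation matrices,
#' differential adjacency, topological overlap, and module detection.
#' Returns a fitted object that the permutation filters
#' ([filter_gene_pairs()], [dispersion_significance()]) consume.
#'
#' @param eset a `PairedExpressionSet`.
#' @param beta soft-threshold exponent (default 6).
#' @param min_module_size smallest reported module (default 10, matching
#'   the convention of testing only modules with more than 10 genes for
#'   enrichment).
#' @param cut_height optional fixed tree-cut height; by default the cut
#'   adapts to the merge-height range (see [cluster_modules()]).
#' @param cut_fraction adaptive cut position (default 0.99).
#' @param method correlation method.
#' @return object of class `"diffcoex"` with elements `correlations`
#'   (a `CorrelationPair`), `adjacency`, `tom`, `partition`, `beta`,
#'   and the call.
#' @export
diffcoex <- function(eset, beta = 6, min_module_size = 10,
                     cut_height = NULL, cut_fraction = 0.99,
                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  cp <- correlation_pair(pairwise_correlation(eset, "pre", method),
                         pairwise_correlation(eset, "post", method),
                         method)
  adj <- differential_adjacency(cp, beta)
  tom <- topological_overlap(adj)
  part <- cluster_modules(tom, min_module_size, cut_height, cut_fraction)
  structure(list(correlations = cp, adjacency = adj, tom = tom,
                 partition = part, beta = beta, eset = eset,
                 call = match.call()),
            class = "diffcoex")
}

#' @export
print.diffcoex <- function(x, ...) {
  cat("Differential co-expression network (beta =", x$beta, ")\n")
  print(x$partition)
  invisible(x)
}

#' @export
summary.diffcoex <- function(object, ...) {
  part <- object$partition
  k <- max(part)
  sizes <- if (k > 0) as.integer(table(part[part > 0])) else integer(0)
  half_delta <- abs(object$correlations$corr_pre -
                    object$correlations$corr_post) / 2
  res <- list(n_genes = length(part), n_modules = k, sizes = sizes,
              assigned = sum(part > 0),
              mean_abs_half_delta = mean(half_delta[upper.tri(half_delta)]))
  class(res) <- "summary.diffcoex"
  res
}

#' @export
print.summary.diffcoex <- function(x, ...) {
  cat("Differential co-expression fit\n")
  cat("  genes:", x$n_genes, "  modules:", x$n_modules,
      "  assigned:", x$assigned, "\n")
  if (x$n_modules)
    cat("  module sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("  mean |delta corr| / 2:",
      format(x$mean_abs_half_delta, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.diffcoex <- function(x, ...) {
  d <- stats::as.dist(1 - x$tom)
  tree <- stats::hclust(d, method = "average")
  plot(tree, labels = FALSE, hang = -1,
       main = "Differential co-expression dendrogram (1 - TOM)",
       xlab = "", sub = "", ...)
  invisible(x)
}

#' Permutation filter on within-module gene pairs
#'
#' For every within-module gene pair the observed statistic is
#' `|corr_pre - corr_post|`.  The null preserves the paired design: each
#' subject's pre/post condition assignment is independently swapped with
#' probability one half, the two correlation matrices are recomputed, and
#' the statistic is collected; `p = (1 + #\{null >= observed\}) /
#' (n_perm + 1)`.  Benjamini-Hochberg correction runs across all tested
#' pairs and pairs above the FDR threshold are removed.
#'
#' @param eset a `PairedExpressionSet`.
#' @param partition a `"ModulePartition"` with at least one module.
#' @param n_perm number of permutations (>= 99).
#' @param fdr_threshold FDR above which a pair is removed (default 0.01).
#' @param seed integer seed for the permutation draws.
#' @param method correlation method.
#' @param drop_genes if `TRUE` (default) genes that lose all their
#'   within-module edges are unassigned from their module.
#' @return list of class `"PairFilterResult"` with `pairs` (data frame:
#'   gene_a, gene_b, module, statistic, p, q, retained) and `partition`
#'   (the possibly pruned partition).
#' @export
filter_gene_pairs <- function(eset, partition, n_perm = 999,
                              fdr_threshold = 0.01, seed = 1,
                              method = c("pearson", "spearman"),
                              drop_genes = TRUE) {
  method <- match.arg(method)
  if (n_perm < 99) warning("n_perm < 99 gives coarse p-value resolution")
  labels <- as.integer(partition)
  names(labels) <- names(partition)
  genes <- names(labels)[labels > 0]
  if (!length(genes)) stop("partition has no module genes")
  sub <- subset_genes(eset, genes)
  pre <- condition_matrix(sub, "pre")
  post <- condition_matrix(sub, "post")
  lab <- labels[genes]

  pair_stats <- function(m_pre, m_post) {
    r1 <- stats::cor(t(m_pre), method = method)
    r2 <- stats::cor(t(m_post), method = method)
    abs(r1 - r2)
  }
  obs_mat <- pair_stats(pre, post)

  same_mod <- outer(lab, lab, `==`) & upper.tri(obs_mat)
  idx <- which(same_mod, arr.ind = TRUE)
  obs <- obs_mat[same_mod]

  set.seed(seed)
  ns <- ncol(pre)
  count <- numeric(length(obs))
  for (b in seq_len(n_perm)) {
    flip <- stats::runif(ns) < 0.5
    p_b <- pre; q_b <- post
    p_b[, flip] <- post[, flip]
    q_b[, flip] <- pre[, flip]
    null_stat <- pair_stats(p_b, q_b)[same_mod]
    count <- count + (null_stat >= obs)
  }
  p <- (1 + count) / (n_perm + 1)
  q <- bh_fdr(p)
  pairs <- data.frame(gene_a = genes[idx[, 1]],
                      gene_b = genes[idx[, 2]],
                      module = lab[idx[, 1]],
                      statistic = obs, p = p, q = q,
                      retained = q <= fdr_threshold,
                      stringsAsFactors = FALSE)
  new_labels <- labels
  if (drop_genes) {
    kept <- unique(c(pairs$gene_a[pairs$retained],
                     pairs$gene_b[pairs$retained]))
    lost <- setdiff(genes, kept)
    new_labels[lost] <- 0L
  }
  structure(list(pairs = pairs,
                 partition = module_partition(
                   new_labels, attr(partition, "min_module_size"),
                   attr(partition, "cut_height"))),
            class = "PairFilterResult")
}

#' @export
print.PairFilterResult <- function(x, ...) {
  cat("Gene-pair permutation filter:",
      sum(x$pairs$retained), "of", nrow(x$pairs), "pairs retained\n")
  invisible(x)
}

#' Module-module dispersion statistic
#'
#' Root mean square of the half correlation differences over the gene
#' pairs connecting two modules: `d = sqrt(mean(((c_pre - c_post)/2)^2))`.
#' For a module against itself the unordered within-module pairs `i < j`
#' are used.  `d = 0` exactly when every involved pairwise correlation is
#' identical across conditions.
#'
#' @param cp a [correlation_pair()].
#' @param genes_a,genes_b character vectors of gene identifiers (identical
#'   for the within-module case).
#' @return nonnegative scalar `d`.
#' @export
module_dispersion <- function(cp, genes_a, genes_b = genes_a) {
  stopifnot(inherits(cp, "CorrelationPair"))
  if (!length(genes_a) || !length(genes_b))
    stop("modules must be non-empty")
  half <- (cp$corr_pre - cp$corr_post) / 2
  if (setequal(genes_a, genes_b) && length(genes_a) == length(genes_b)) {
    if (length(genes_a) < 2)
      stop("within-module dispersion needs at least 2 genes")
    s <- half[genes_a, genes_a, drop = FALSE]^2
    sqrt(sum(s[upper.tri(s)]) / (length(genes_a) *
                                 (length(genes_a) - 1) / 2))
  } else {
    sqrt(mean(half[genes_a, genes_b, drop = FALSE]^2))
  }
}

#' Significance of module-module dispersion
#'
#' Builds the null by constructing `n_random` random partitions with the
#' same multiset of module sizes (genes drawn without replacement from the
#' analyzed gene universe), computing the dispersion statistic for every
#' pair of random clusters, and pooling null values by unordered size
#' pair.  `p = (1 + #\{null d >= observed\}) / (n_null + 1)` within the
#' matching size pair, BH-corrected across all module pairs (including
#' each module with itself); pairs with `q <= fdr_threshold` are network
#' edges.
#'
#' @param eset a `PairedExpressionSet` over the analyzed gene universe.
#' @param partition a `"ModulePartition"` with >= 1 module (>= 2 for
#'   between-module edges).
#' @param n_random number of random cluster sets (default 1000).
#' @param fdr_threshold edge threshold (default 0.10).
#' @param seed integer seed.
#' @param method correlation method.
#' @param null `"size_matched"` (default) compares each observed pair with
#'   null pairs of the same sizes; `"pooled"` pools all null values.
#' @return data frame of class `"DispersionResult"`: module_a, module_b,
#'   size_a, size_b, d, p, q, edge.
#' @export
dispersion_significance <- function(eset, partition, n_random = 1000,
                                    fdr_threshold = 0.10, seed = 1,
                                    method = c("pearson", "spearman"),
                                    null = c("size_matched", "pooled")) {
  method <- match.arg(method)
  null <- match.arg(null)
  if (n_random < 100)
    warning("n_random < 100 gives coarse p-value resolution")
  labels <- as.integer(partition)
  names(labels) <- names(partition)
  k <- max(labels)
  if (k < 1) stop("partition has no modules")
  cp <- correlation_pair(pairwise_correlation(eset, "pre", method),
                         pairwise_correlation(eset, "post", method),
                         method)
  s_half <- ((cp$corr_pre - cp$corr_post) / 2)^2
  universe <- eset$gene_ids
  sizes <- as.integer(table(factor(labels[labels > 0],
                                   levels = seq_len(k))))

  block_d <- function(members) {
    # members: list of index vectors into universe
    out <- list()
    kk <- length(members)
    for (a in seq_len(kk)) for (b in a:kk) {
      ia <- members[[a]]; ib <- members[[b]]
      d <- if (a == b) {
        s <- s_half[ia, ia, drop = FALSE]
        sqrt(sum(s[upper.tri(s)]) / (length(ia) * (length(ia) - 1) / 2))
      } else {
        sqrt(mean(s_half[ia, ib, drop = FALSE]))
      }
      out[[length(out) + 1L]] <- c(a, b, d)
    }
    do.call(rbind, out)
  }

  obs_members <- lapply(seq_len(k), function(m)
    which(labels[universe] == m))
  obs <- block_d(obs_members)

  size_key <- function(sa, sb) paste(pmin(sa, sb), pmax(sa, sb), sep = "x")
  null_pool <- list()
  set.seed(seed)
  for (r in seq_len(n_random)) {
    draw <- sample(seq_along(universe), sum(sizes))
    members <- split(draw, rep(seq_len(k), sizes))
    nb <- block_d(members)
    keys <- if (null == "pooled") rep("all", nrow(nb)) else
      size_key(sizes[nb[, 1]], sizes[nb[, 2]])
    for (u in unique(keys))
      null_pool[[u]] <- c(null_pool[[u]], nb[keys == u, 3])
  }

  p <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    key <- if (null == "pooled") "all" else
      size_key(sizes[obs[i, 1]], sizes[obs[i, 2]])
    pool <- null_pool[[key]]
    p[i] <- (1 + sum(pool >= obs[i, 3])) / (length(pool) + 1)
  }
  q <- bh_fdr(p)
  res <- data.frame(module_a = as.integer(obs[, 1]),
                    module_b = as.integer(obs[, 2]),
                    size_a = sizes[obs[, 1]],
                    size_b = sizes[obs[, 2]],
                    d = obs[, 3], p = p, q = q,
                    edge = q <= fdr_threshold)
  class(res) <- c("DispersionResult", "data.frame")
  res
}

#' Module-level network graph
#'
#' Nodes are the modules (annotated with size); edges are the module pairs
#' whose dispersion passed the FDR filter, carrying `d` and `q` as
#' attributes.  Self-pairs (within-module dispersion) become a node
#' attribute `within_q` rather than loops.
#'
#' @param partition a `"ModulePartition"`.
#' @param dispersion a `"DispersionResult"`.
#' @return an [igraph::graph][igraph] object.
#' @export
build_module_graph <- function(partition, dispersion) {
  labels <- as.integer(partition)
  k <- max(labels)
  sizes <- as.integer(table(factor(labels[labels > 0],
                                   levels = seq_len(k))))
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  igraph::V(g)$name <- sprintf("M%d", seq_len(k))
  igraph::V(g)$size <- sizes
  within <- dispersion[dispersion$module_a == dispersion$module_b, ]
  wq <- rep(NA_real_, k)
  wq[within$module_a] <- within$q
  igraph::V(g)$within_q <- wq
  between <- dispersion[dispersion$module_a != dispersion$module_b &
                          dispersion$edge, ]
  if (nrow(between)) {
    el <- rbind(sprintf("M%d", between$module_a),
                sprintf("M%d", between$module_b))
    g <- igraph::add_edges(g, as.vector(el))
    igraph::E(g)$d <- between$d
    igraph::E(g)$q <- between$q
  }
  g
}

#' Write module assignments as two-column tab-delimited text
#' @param partition a `"ModulePartition"`.
#' @param path output path.
#' @export
write_modules <- function(partition, path) {
  utils::write.table(data.frame(gene = names(partition),
                                module = as.integer(partition)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a module graph as GraphML and SIF-style edge list
#'
#' @param graph module graph from [build_module_graph()].
#' @param prefix output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>.sif` and `<prefix>.edge_attributes.tsv`.
#' @export
write_module_graph <- function(graph, prefix) {
  igraph::write_graph(graph, paste0(prefix, ".graphml"),
                      format = "graphml")
  el <- igraph::as_edgelist(graph)
  sif <- if (nrow(el)) sprintf("%s\tdiffcoex\t%s", el[, 1], el[, 2])
         else character(0)
  writeLines(sif, paste0(prefix, ".sif"))
  attrs <- if (nrow(el)) data.frame(module_a = el[, 1], module_b = el[, 2],
                                    d = igraph::E(graph)$d,
                                    q = igraph::E(graph)$q)
           else data.frame(module_a = character(0), module_b = character(0),
                           d = numeric(0), q = numeric(0))
  utils::write.table(attrs, paste0(prefix, ".edge_attributes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
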
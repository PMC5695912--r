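# Regulator-pathway-phenotype integration: candidate regulator genes are
# linked to gene sets through enrichment of their differentially
# co-expressed neighborhoods, and to phenotypes through regression of the
# training-induced phenotype change on baseline expression.  Node degree
# in the merged graph ranks candidate regulators; the seed-gene
# condition-specific networks contrast a regulator's pathway neighborhood
# before and after training.

#' Differential co-expression of every gene with one regulator
#'
#' For each gene g (other than the regulator) the score is
#' `|corr_pre(g, reg) - corr_post(g, reg)|`; significance uses the paired
#' condition-shuffle permutation scheme of [filter_gene_pairs()]
#' restricted to the pairs (g, regulator), with BH correction across
#' genes.
#'
#' @param eset a `PairedExpressionSet`.
#' @param regulator gene identifier present in `eset`.
#' @param n_perm number of permutations (default 499).
#' @param fdr_threshold genes with `q <= fdr_threshold` form the
#'   regulator's rewired neighborhood (default 0.10).
#' @param seed integer seed.
#' @param method correlation method.
#' @return data frame of class `"RegulatorScores"`: gene, score, p, q,
#'   significant; attribute `"regulator"`.
#' @export
regulator_diffcoex_scores <- function(eset, regulator, n_perm = 499,
                                      fdr_threshold = 0.10, seed = 1,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!regulator %in% eset$gene_ids)
    stop("regulator gene not in the expression set: ", regulator)
  pre <- condition_matrix(eset, "pre")
  post <- condition_matrix(eset, "post")
  others <- setdiff(eset$gene_ids, regulator)

  # correlation of one gene against all rows, without matrix transposes:
  # kept lean because it sits inside the permutation loop; Spearman is
  # Pearson on within-condition ranks, computed after any label flip
  cor_vec <- function(m, v) {
    if (method == "spearman") {
      m <- t(apply(m, 1, rank))
      v <- rank(v)
    }
    mc <- m - rowMeans(m)
    vc <- v - mean(v)
    drop(mc %*% vc) / sqrt(rowSums(mc * mc) * sum(vc * vc))
  }
  reg_scores <- function(m_pre, m_post) {
    abs(cor_vec(m_pre[others, , drop = FALSE], m_pre[regulator, ]) -
        cor_vec(m_post[others, , drop = FALSE], m_post[regulator, ]))
  }
  obs <- reg_scores(pre, post)

  set.seed(seed)
  ns <- ncol(pre)
  if (method == "pearson") {
    # batched null: under a pre/post flip of subject set S, every moment
    # of the flipped condition splits into a pre part (weights 1 - f)
    # and a post part (weights f), so all n_perm statistics come from a
    # handful of matrix products
    f_mat <- matrix(as.numeric(stats::runif(ns * n_perm) < 0.5),
                    ns, n_perm)
    g_mat <- 1 - f_mat
    x_pre <- pre[others, , drop = FALSE]
    x_post <- post[others, , drop = FALSE]
    y_pre <- pre[regulator, ]
    y_post <- post[regulator, ]
    mixed_cor <- function(w_pre, w_post) {
      sxy <- (x_pre * rep(y_pre, each = length(others))) %*% w_pre +
        (x_post * rep(y_post, each = length(others))) %*% w_post
      sx <- x_pre %*% w_pre + x_post %*% w_post
      sxx <- (x_pre^2) %*% w_pre + (x_post^2) %*% w_post
      sy <- drop(y_pre %*% w_pre + y_post %*% w_post)
      syy <- drop(y_pre^2 %*% w_pre + y_post^2 %*% w_post)
      num <- sxy - sx * rep(sy, each = length(others)) / ns
      den <- sqrt((sxx - sx^2 / ns) *
                  rep(syy - sy^2 / ns, each = length(others)))
      num / den
    }
    null_stat <- abs(mixed_cor(g_mat, f_mat) - mixed_cor(f_mat, g_mat))
    count <- rowSums(null_stat >= obs)
  } else {
    count <- numeric(length(obs))
    for (b in seq_len(n_perm)) {
      flip <- stats::runif(ns) < 0.5
      p_b <- pre; q_b <- post
      p_b[, flip] <- post[, flip]
      q_b[, flip] <- pre[, flip]
      count <- count + (reg_scores(p_b, q_b) >= obs)
    }
  }
  p <- (1 + count) / (n_perm + 1)
  q <- bh_fdr(p)
  res <- data.frame(gene = others, score = obs, p = p, q = q,
                    significant = q <= fdr_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "regulator") <- regulator
  class(res) <- c("RegulatorScores", "data.frame")
  res
}

#' Regulator-to-pathway edges by neighborhood enrichment
#'
#' Over-representation of the regulator's significantly rewired
#' neighborhood in each gene set; every enriched set becomes an edge.
#'
#' @param scores a `"RegulatorScores"` result.
#' @param collection a `"GeneSetCollection"`.
#' @param universe character vector of measured genes.
#' @param fdr_threshold edge threshold on the enrichment q (default 0.10).
#' @param min_set minimum in-universe set size (default 5).
#' @return data frame of edges: from (regulator), to (set), q, evidence.
#' @export
regulator_pathway_edges <- function(scores, collection, universe,
                                    fdr_threshold = 0.10, min_set = 5) {
  regulator <- attr(scores, "regulator")
  sig <- scores$gene[scores$significant]
  empty <- data.frame(from = character(0), to = character(0),
                      from_type = character(0), to_type = character(0),
                      q = numeric(0), evidence = character(0))
  if (!length(sig)) {
    warning("no significant neighborhood for regulator ", regulator)
    return(empty)
  }
  if (!length(collection)) return(empty)
  enr <- ora_collection(sig, collection, universe,
                        fdr_threshold = fdr_threshold, min_set = min_set)
  hit <- enr[enr$enriched, ]
  if (!nrow(hit)) return(empty)
  data.frame(from = regulator, to = hit$set,
             from_type = "regulator_gene", to_type = "gene_set",
             q = hit$q, evidence = "enrichment",
             stringsAsFactors = FALSE)
}

#' Regulator-to-phenotype edges by baseline regression
#'
#' For every (regulator, phenotype) pair, ordinary least squares of the
#' training-induced phenotype change on the subject's baseline (pre)
#' expression of the regulator; two-sided slope p-values, BH across the
#' whole grid, edges at `q <= fdr_threshold`.
#'
#' @param eset a `PairedExpressionSet`.
#' @param phenotypes a `"PhenotypeTable"`.
#' @param regulators character vector of regulator gene identifiers.
#' @param fdr_threshold edge threshold (default 0.10).
#' @param response `"delta"` (default, post - pre) or `"percent"`
#'   (100 * delta / pre).
#' @return list with `edges` (data frame as in
#'   [regulator_pathway_edges()]) and `fits` (data frame: regulator,
#'   phenotype, slope, p, q).
#' @export
regulator_phenotype_edges <- function(eset, phenotypes, regulators,
                                      fdr_threshold = 0.10,
                                      response = c("delta", "percent")) {
  response <- match.arg(response)
  missing <- setdiff(regulators, eset$gene_ids)
  if (length(missing))
    stop("regulators not in the expression set: ",
         paste(missing, collapse = ", "))
  pre <- condition_matrix(eset, "pre")
  rows <- list()
  for (ph in unique(phenotypes$measurement)) {
    tab <- phenotypes[phenotypes$measurement == ph, ]
    y <- if (response == "delta") tab$delta else 100 * tab$delta / tab$pre
    names(y) <- tab$subject
    common <- intersect(colnames(pre), tab$subject)
    y <- y[common]
    ok <- is.finite(y)
    for (reg in regulators) {
      x <- pre[reg, common][ok]
      yy <- y[ok]
      if (length(yy) < 4) {
        warning(sprintf("fewer than 4 complete cases for (%s, %s)",
                        reg, ph))
        next
      }
      if (stats::var(x) == 0) {
        warning(sprintf("zero-variance baseline for %s: pair skipped",
                        reg))
        next
      }
      fit <- stats::lm(yy ~ x)
      cf <- summary(fit)$coefficients
      rows[[length(rows) + 1L]] <-
        data.frame(regulator = reg, phenotype = ph,
                   slope = cf["x", "Estimate"],
                   p = cf["x", "Pr(>|t|)"],
                   stringsAsFactors = FALSE)
    }
  }
  fits <- do.call(rbind, rows)
  if (is.null(fits))
    return(list(edges = data.frame(from = character(0), to = character(0),
                                   from_type = character(0),
                                   to_type = character(0),
                                   q = numeric(0), evidence = character(0)),
                fits = data.frame()))
  fits$q <- bh_fdr(fits$p)
  hit <- fits[fits$q <= fdr_threshold, ]
  edges <- data.frame(from = hit$regulator, to = hit$phenotype,
                      from_type = rep("regulator_gene", nrow(hit)),
                      to_type = rep("phenotype", nrow(hit)),
                      q = hit$q,
                      evidence = rep("regression", nrow(hit)),
                      stringsAsFactors = FALSE)
  list(edges = edges, fits = fits)
}

#' Assemble the regulator-pathway-phenotype integration graph
#'
#' Merges edge lists into one simple graph: one edge per node pair (the
#' best, i.e. smallest, q is kept), nodes typed `regulator_gene`,
#' `gene_set` or `phenotype`.  Edges must connect a regulator gene to a
#' node of another type.
#'
#' @param ... edge data frames with columns from, to, from_type, to_type,
#'   q, evidence (as produced by the edge builders); may also be passed as
#'   a single list.
#' @return an [igraph::graph][igraph] of class with vertex attribute
#'   `type` and edge attributes `q`, `evidence`.
#' @export
assemble_graph <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.data.frame(parts[[1]]) == FALSE &&
      is.list(parts[[1]])) parts <- parts[[1]]
  edges <- do.call(rbind, parts)
  if (is.null(edges) || !nrow(edges)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  bad <- edges$from_type != "regulator_gene" |
    !(edges$to_type %in% c("gene_set", "phenotype"))
  if (any(bad))
    stop("edges must link a regulator_gene to a gene_set or phenotype")
  # deterministic merge: sort, keep best q per node pair
  key <- paste(edges$from, edges$to, sep = "\r")
  edges <- edges[order(key, edges$q), ]
  edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), ]
  nodes <- unique(rbind(
    data.frame(name = edges$from, type = edges$from_type),
    data.frame(name = edges$to, type = edges$to_type)))
  nodes <- nodes[order(nodes$name), ]
  if (anyDuplicated(nodes$name))
    stop("node appears with more than one type")
  g <- igraph::graph_from_data_frame(
    edges[c("from", "to", "q", "evidence")],
    directed = FALSE, vertices = nodes)
  g
}

#' Node degrees of an integration graph, ranked
#'
#' @param graph graph from [assemble_graph()].
#' @return data frame: node, type, degree; sorted by decreasing degree
#'   with deterministic tie-break by node name.
#' @export
node_degrees <- function(graph) {
  if (igraph::vcount(graph) == 0)
    return(data.frame(node = character(0), type = character(0),
                      degree = integer(0)))
  deg <- igraph::degree(graph)
  res <- data.frame(node = igraph::V(graph)$name,
                    type = igraph::V(graph)$type,
                    degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$degree, res$node), ]
  rownames(res) <- NULL
  res
}

#' Condition-specific seed-gene pathway network
#'
#' Correlates every gene with the seed gene within one condition, converts
#' r to a two-sided p through `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom, BH-corrects, and tests the significant
#' genes for gene-set over-representation.  The result is a star graph
#' seed -> enriched sets whose seed degree (number of enriched sets)
#' summarises how broad the seed's co-expression neighborhood is in that
#' condition.
#'
#' @param eset a `PairedExpressionSet`.
#' @param seed_gene seed gene identifier.
#' @param condition `"pre"` or `"post"`.
#' @param collection a `"GeneSetCollection"`.
#' @param corr_fdr FDR threshold on the correlation q (default 0.05).
#' @param enrich_fdr FDR threshold on the enrichment q (default 0.10).
#' @param min_set minimum in-universe set size (default 5).
#' @param method correlation method.
#' @return list of class `"SeedNetwork"`: `correlations` (gene, r, p, q,
#'   significant), `significant_genes`, `enrichment`, `graph` (star
#'   igraph), `degree`, `condition`, `seed_gene`.
#' @export
seed_condition_network <- function(eset, seed_gene,
                                   condition = c("pre", "post"),
                                   collection, corr_fdr = 0.05,
                                   enrich_fdr = 0.10, min_set = 5,
                                   method = c("pearson", "spearman")) {
  condition <- match.arg(condition)
  method <- match.arg(method)
  if (!seed_gene %in% eset$gene_ids)
    stop("seed gene not in the expression set: ", seed_gene)
  m <- condition_matrix(eset, condition)
  n <- ncol(m)
  if (n < 4) stop("need at least 4 samples in the condition")
  others <- setdiff(eset$gene_ids, seed_gene)
  r <- drop(stats::cor(t(m[others, , drop = FALSE]), m[seed_gene, ],
                       method = method))
  r2 <- pmin(r^2, 1)
  p <- numeric(length(r))
  exact <- abs(r) >= 1 - 1e-15
  if (any(exact)) {
    warning("correlation of +/-1: p set to minimum representable")
    p[exact] <- .Machine$double.xmin
  }
  tval <- r[!exact] * sqrt((n - 2) / (1 - r2[!exact]))
  p[!exact] <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  q <- bh_fdr(p)
  corr_tab <- data.frame(gene = others, r = r, p = p, q = q,
                         significant = q <= corr_fdr,
                         stringsAsFactors = FALSE, row.names = NULL)
  sig <- corr_tab$gene[corr_tab$significant]
  enr <- if (length(sig) && length(collection)) {
    ora_collection(sig, collection, eset$gene_ids,
                   fdr_threshold = enrich_fdr, min_set = min_set)
  } else NULL
  hits <- if (!is.null(enr)) enr$set[enr$enriched] else character(0)
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, 1 + length(hits),
                            name = c(seed_gene, hits),
                            type = c("regulator_gene",
                                     rep("gene_set", length(hits))))
  if (length(hits))
    g <- igraph::add_edges(g, as.vector(rbind(seed_gene, hits)))
  structure(list(correlations = corr_tab, significant_genes = sig,
                 enrichment = enr, graph = g, degree = length(hits),
                 condition = condition, seed_gene = seed_gene),
            class = "SeedNetwork")
}

#' @export
print.SeedNetwork <- function(x, ...) {
  cat(sprintf(
    "Seed network for %s (%s): %d correlated genes, degree %d\n",
    x$seed_gene, x$condition, length(x$significant_genes), x$degree))
  invisible(x)
}

#' Write an integration graph as GraphML plus a degree table
#'
#' @param graph graph from [assemble_graph()].
#' @param prefix path prefix; writes `<prefix>.graphml` and
#'   `<prefix>.degrees.tsv`.
#' @export
write_integration_graph <- function(graph, prefix) {
  igraph::write_graph(graph, paste0(prefix, ".graphml"),
                      format = "graphml")
  utils::write.table(node_degrees(graph), paste0(prefix, ".degrees.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
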
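# Gene-set enrichment: over-representation (hypergeometric) tests against
# a collection, and a ranked running-sum (GSEA-style) statistic with a
# leading-edge ("core enriched") member list.  The universe is always the
# set of measured genes, not the genome, so enrichment is assessed against
# what could have been detected.

#' Upper-tail hypergeometric enrichment p-value
#'
#' `p = P(X >= overlap)` where `X` is the overlap of a random query of the
#' same size with the gene set, both restricted to the universe.
#'
#' @param query character vector of query genes (must lie in the universe).
#' @param gene_set character vector of set members; intersected with the
#'   universe before testing.
#' @param universe character vector of measured genes.
#' @return list with `p`, `overlap`, `set_size` (in-universe),
#'   `query_size`, `universe_size`, `overlap_genes`.
#' @export
hypergeometric_test <- function(query, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty")
  query <- unique(query)
  if (!length(query)) stop("query is empty")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  set_in <- intersect(unique(gene_set), universe)
  hits <- intersect(query, set_in)
  k <- length(hits)
  p <- stats::phyper(k - 1, length(set_in),
                     length(universe) - length(set_in),
                     length(query), lower.tail = FALSE)
  list(p = p, overlap = k, set_size = length(set_in),
       query_size = length(query), universe_size = length(universe),
       overlap_genes = hits)
}

#' Over-representation analysis against a gene-set collection
#'
#' One hypergeometric test per set with at least `min_set` in-universe
#' members, BH correction across the tested sets.
#'
#' @param query character vector of query genes.
#' @param collection a `"GeneSetCollection"`.
#' @param universe character vector of measured genes.
#' @param fdr_threshold sets with `q <= fdr_threshold` are flagged
#'   enriched (default 0.10).
#' @param min_set minimum in-universe set size (default 5).
#' @return data frame of class `"EnrichmentResult"`: set, overlap,
#'   set_size, query_size, universe_size, p, q, enriched,
#'   overlap_genes (comma-separated).
#' @export
ora_collection <- function(query, collection, universe,
                           fdr_threshold = 0.10, min_set = 5) {
  universe <- unique(universe)
  sizes <- vapply(collection, function(s)
    length(intersect(s, universe)), integer(1))
  keep <- names(collection)[sizes >= min_set]
  if (!length(keep)) {
    warning("no gene sets with at least ", min_set,
            " in-universe members")
    res <- data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      q = numeric(0), enriched = logical(0),
                      overlap_genes = character(0))
    class(res) <- c("EnrichmentResult", "data.frame")
    return(res)
  }
  rows <- lapply(keep, function(nm) {
    h <- hypergeometric_test(query, collection[[nm]], universe)
    data.frame(set = nm, overlap = h$overlap, set_size = h$set_size,
               query_size = h$query_size, universe_size = h$universe_size,
               p = h$p,
               overlap_genes = paste(h$overlap_genes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res$enriched <- res$q <= fdr_threshold
  res <- res[order(res$q, res$p, res$set),
             c("set", "overlap", "set_size", "query_size",
               "universe_size", "p", "q", "enriched", "overlap_genes")]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Ranked (GSEA-style) enrichment of one gene set
#'
#' Weighted Kolmogorov-Smirnov running sum over the ranking: at each hit
#' the sum rises by `|score|^weight_exponent` (normalised over the hits),
#' at each miss it falls by `1 / (N - set size)`.  The enrichment score is
#' the extremum of the running sum; the leading edge ("core enriched"
#' members) are the hits at or before a positive extremum (at or after a
#' negative one).  Significance is by gene-label permutation: random sets
#' of the same size drawn from the ranked list.
#'
#' @param scores named numeric vector of ranking scores (no duplicate
#'   names); sorted internally in decreasing order.
#' @param gene_set character vector of set members; must intersect the
#'   ranked list.
#' @param n_perm number of permutations (default 999).
#' @param weight_exponent hit-weight exponent (default 1; 0 gives the
#'   classical unweighted KS statistic).
#' @param seed integer seed.
#' @return list of class `"GseaResult"`: `es`, `leading_edge`, `p`,
#'   `running_sum`, `hit_positions`.
#' @export
gsea_ranked <- function(scores, gene_set, n_perm = 999,
                        weight_exponent = 1, seed = 1) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be uniquely named by gene")
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  hits <- names(scores) %in% gene_set
  if (!any(hits)) stop("gene set is disjoint from the ranked list")

  es_of <- function(hits) {
    n <- length(scores)
    w <- abs(scores)^weight_exponent
    inc <- numeric(n)
    inc[hits] <- w[hits] / sum(w[hits])
    inc[!hits] <- -1 / (n - sum(hits))
    rs <- cumsum(inc)
    rs[which.max(abs(rs))]
  }
  running <- local({
    n <- length(scores)
    w <- abs(scores)^weight_exponent
    inc <- numeric(n)
    inc[hits] <- w[hits] / sum(w[hits])
    inc[!hits] <- -1 / (n - sum(hits))
    cumsum(inc)
  })
  peak <- which.max(abs(running))
  es <- running[peak]
  hit_pos <- which(hits)
  leading <- if (es >= 0) names(scores)[hit_pos[hit_pos <= peak]]
             else names(scores)[hit_pos[hit_pos >= peak]]

  set.seed(seed)
  m <- sum(hits)
  count <- 0
  for (b in seq_len(n_perm)) {
    hb <- logical(length(scores))
    hb[sample(length(scores), m)] <- TRUE
    if (abs(es_of(hb)) >= abs(es)) count <- count + 1
  }
  p <- (1 + count) / (n_perm + 1)
  structure(list(es = es, leading_edge = leading, p = p,
                 running_sum = running, hit_positions = hit_pos),
            class = "GseaResult")
}

#' @export
print.GseaResult <- function(x, ...) {
  cat("Ranked enrichment: ES =", format(x$es, digits = 4),
      ", p =", format(x$p, digits = 4), ",",
      length(x$leading_edge), "leading-edge genes\n")
  invisible(x)
}
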
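# Paired differential expression in the SAM style: a moderated paired
# statistic d = r / (s + s0) whose fudge factor s0 stabilises the variance
# of d across the range of gene-wise standard errors, with significance
# from sign-flip permutations of the subject-wise differences.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; a thin validating wrapper around
#' [stats::p.adjust()] that preserves input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Paired SAM-style differential expression
#'
#' For each gene, `r` is the mean over subjects of the paired difference
#' (post - pre), `s` its standard error, and the statistic is
#' `d = r / (s + s0)`.  The fudge factor `s0` is, by default, the
#' percentile of the `s` distribution that minimises the coefficient of
#' variation of a robust spread of `d` across bins of `s` (the
#' variance-stabilising choice); `"median"` and a fixed numeric value are
#' also accepted.  The null flips the sign of each subject's difference
#' vector independently; the two-sided p-value is
#' `(1 + #\{|d_null| >= |d_obs|\}) / (n_perm + 1)`, BH-corrected.
#'
#' @param eset a `PairedExpressionSet` with >= 4 subjects.
#' @param n_perm number of sign-flip permutations (>= 99 recommended).
#' @param s0_rule `"cv_min"` (default), `"median"`, or a fixed
#'   nonnegative number.
#' @param fdr_threshold significance threshold on q (default 0.05).
#' @param seed integer seed.
#' @return object of class `"sam_paired"`: data frame `table` with
#'   columns gene, r, s, d, p, q, significant; plus `s0` and the call.
#' @export
sam_paired <- function(eset, n_perm = 999, s0_rule = "cv_min",
                       fdr_threshold = 0.05, seed = 1) {
  stopifnot(inherits(eset, "PairedExpressionSet"))
  diffs <- paired_differences(eset)
  ns <- ncol(diffs)
  if (ns < 4) stop("need at least 4 subjects")
  if (n_perm < 99) warning("n_perm < 99 gives coarse p-value resolution")

  se_of <- function(m, means) {
    # standard error of the row means, vectorised
    sqrt(pmax(rowSums(m * m) - ns * means^2, 0) / (ns - 1)) / sqrt(ns)
  }
  r <- rowMeans(diffs)
  s <- se_of(diffs, r)
  s0 <- resolve_s0(s, r, s0_rule)
  if (s0 == 0 && any(s == 0))
    stop("zero-variance gene with s0 = 0: statistic undefined")
  d <- r / (s + s0)

  set.seed(seed)
  count <- numeric(nrow(diffs))
  abs_d <- abs(d)
  sq <- rowSums(diffs * diffs) # invariant under sign flips
  for (b in seq_len(n_perm)) {
    signs <- sample(c(-1, 1), ns, replace = TRUE)
    rb <- drop(diffs %*% signs) / ns
    sb <- sqrt(pmax(sq - ns * rb^2, 0) / (ns - 1)) / sqrt(ns)
    count <- count + (abs(rb / (sb + s0)) >= abs_d)
  }
  p <- (1 + count) / (n_perm + 1)
  q <- bh_fdr(p)
  tab <- data.frame(gene = rownames(diffs), r = r, s = s, d = d,
                    p = p, q = q, significant = q <= fdr_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, s0 = s0, n_perm = n_perm,
                 fdr_threshold = fdr_threshold, call = match.call()),
            class = "sam_paired")
}

# s0 selection: candidate percentiles of s; choose the one minimising the
# coefficient of variation of mad(d) across quantile bins of s.
resolve_s0 <- function(s, r, s0_rule) {
  if (is.numeric(s0_rule)) {
    if (s0_rule < 0) stop("fixed s0 must be nonnegative")
    return(s0_rule)
  }
  if (identical(s0_rule, "median")) return(stats::median(s))
  if (!identical(s0_rule, "cv_min")) stop("unknown s0 rule: ", s0_rule)
  cand <- stats::quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE)
  n_bins <- min(10L, max(2L, floor(length(s) / 10)))
  bins <- cut(rank(s, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    spread <- tapply(d, bins, stats::mad)
    if (mean(spread) == 0) return(Inf)
    stats::sd(spread) / mean(spread)
  }, numeric(1))
  cand[which.min(cv)]
}

#' @export
print.sam_paired <- function(x, ...) {
  cat("Paired SAM-style analysis:", nrow(x$table), "genes, s0 =",
      format(x$s0, digits = 4), "\n")
  cat(sum(x$table$significant), "genes significant at FDR",
      x$fdr_threshold, "\n")
  invisible(x)
}

#' Write a SAM result table as tab-delimited text
#' @param x a `"sam_paired"` object.
#' @param path output path.
#' @export
write_sam <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fold-change and p-value filter
#'
#' Selects genes with `|log2fc| > fc_threshold` AND `p < p_threshold`
#' (both inequalities strict).
#'
#' @param log2fc named numeric vector of log2 fold changes.
#' @param p named numeric vector of p-values on the same genes.
#' @param fc_threshold absolute log2 fold-change cutoff (default 1).
#' @param p_threshold p-value cutoff (default 0.05).
#' @return character vector of selected gene identifiers.
#' @export
fc_p_filter <- function(log2fc, p, fc_threshold = 1, p_threshold = 0.05) {
  if (is.null(names(log2fc)) || is.null(names(p)))
    stop("log2fc and p must be named by gene")
  if (!setequal(names(log2fc), names(p)) ||
      length(log2fc) != length(p))
    stop("log2fc and p gene identifiers do not match")
  p <- p[names(log2fc)]
  names(log2fc)[abs(log2fc) > fc_threshold & p < p_threshold]
}
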
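#' Paired two-condition expression set
#'
#' Container for a genes x samples matrix of log2 expression values in which
#' every subject contributes exactly one sample per condition ("pre" and
#' "post").  This is the object that all network inference in the package
#' consumes: correlations are always computed within a condition, with
#' columns aligned on subjects so that paired permutation schemes are
#' well defined.
#'
#' @param values numeric matrix, genes in rows, samples in columns; all
#'   entries must be finite.
#' @param subject_ids character vector, one entry per column of `values`,
#'   naming the subject each sample belongs to.
#' @param condition_labels character vector, one entry per column, each
#'   either `"pre"` or `"post"`.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#'
#' @return An object of class `"PairedExpressionSet"`: a list with elements
#'   `values`, `gene_ids`, `subject_ids`, `condition_labels` and `subjects`
#'   (the sorted unique subject identifiers).
#' @export
paired_expression_set <- function(values, subject_ids, condition_labels,
                                  gene_ids = rownames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric")
  if (is.null(gene_ids))
    stop("gene identifiers are required (rownames or `gene_ids`)")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values))
    stop("length of gene_ids does not match the number of rows")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample %d",
                 gene_ids[bad[1]], bad[2]))
  }
  subject_ids <- as.character(subject_ids)
  condition_labels <- as.character(condition_labels)
  if (length(subject_ids) != ncol(values) ||
      length(condition_labels) != ncol(values))
    stop("subject_ids and condition_labels must have one entry per sample")
  if (!all(condition_labels %in% c("pre", "post")))
    stop("condition labels must be 'pre' or 'post'")
  subjects <- sort(unique(subject_ids))
  for (cond in c("pre", "post")) {
    tab <- table(factor(subject_ids[condition_labels == cond],
                        levels = subjects))
    if (any(tab != 1L)) {
      off <- names(tab)[tab != 1L]
      stop(sprintf("subjects without exactly one '%s' sample: %s",
                   cond, paste(off, collapse = ", ")))
    }
  }
  rownames(values) <- gene_ids
  structure(list(values = values,
                 gene_ids = gene_ids,
                 subject_ids = subject_ids,
                 condition_labels = condition_labels,
                 subjects = subjects),
            class = "PairedExpressionSet")
}

#' @export
print.PairedExpressionSet <- function(x, ...) {
  cat("PairedExpressionSet:", length(x$gene_ids), "genes,",
      length(x$subjects), "subjects (paired pre/post)\n")
  invisible(x)
}

#' @export
dim.PairedExpressionSet <- function(x) dim(x$values)

#' Extract the genes x subjects matrix of one condition
#'
#' Columns are ordered by the sorted subject identifiers, so the matrices
#' for "pre" and "post" are subject-aligned.
#'
#' @param x a `PairedExpressionSet`.
#' @param condition `"pre"` or `"post"`.
#' @return numeric matrix, genes x subjects, columns named by subject.
#' @export
condition_matrix <- function(x, condition = c("pre", "post")) {
  condition <- match.arg(condition)
  stopifnot(inherits(x, "PairedExpressionSet"))
  idx <- which(x$condition_labels == condition)
  idx <- idx[match(x$subjects, x$subject_ids[idx])]
  m <- x$values[, idx, drop = FALSE]
  colnames(m) <- x$subjects
  m
}

#' Per-subject paired differences (post minus pre)
#'
#' @param x a `PairedExpressionSet`.
#' @return numeric matrix, genes x subjects, of post - pre differences.
#' @export
paired_differences <- function(x) {
  condition_matrix(x, "post") - condition_matrix(x, "pre")
}

#' Swap the pre/post labels of selected subjects
#'
#' Utility behind the paired permutation null: for each subject in `flip`
#' the pre and post samples exchange roles while the pairing is preserved.
#'
#' @param x a `PairedExpressionSet`.
#' @param flip logical vector over `x$subjects` (or subject names).
#' @return a `PairedExpressionSet` with the labels exchanged.
#' @export
flip_conditions <- function(x, flip) {
  stopifnot(inherits(x, "PairedExpressionSet"))
  if (is.character(flip)) flip <- x$subjects %in% flip
  stopifnot(is.logical(flip), length(flip) == length(x$subjects))
  labels <- x$condition_labels
  swap <- x$subject_ids %in% x$subjects[flip]
  labels[swap] <- ifelse(labels[swap] == "pre", "post", "pre")
  y <- x
  y$condition_labels <- labels
  y
}

#' Restrict an expression set to a subset of genes
#'
#' @param x a `PairedExpressionSet`.
#' @param genes character vector of gene identifiers to keep.
#' @return a `PairedExpressionSet` over the requested genes, in the
#'   requested order.
#' @export
subset_genes <- function(x, genes) {
  stopifnot(inherits(x, "PairedExpressionSet"))
  missing <- setdiff(genes, x$gene_ids)
  if (length(missing))
    stop("genes absent from the expression set: ",
         paste(missing, collapse = ", "))
  paired_expression_set(x$values[genes, , drop = FALSE],
                        x$subject_ids, x$condition_labels, gene_ids = genes)
}
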
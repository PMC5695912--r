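# Readers and writers for the plain-text formats the pipeline exchanges:
# tab-delimited expression matrices, subject/condition maps, GMT gene-set
# collections and phenotype tables.

#' Read a paired expression matrix from tab-delimited text
#'
#' The file has a header row of sample identifiers, gene identifiers in the
#' first column, and log2 expression values in the remaining cells.  The
#' condition map assigns every sample to a subject and a condition.
#'
#' @param path path to the matrix file.
#' @param condition_map data frame with columns `sample`, `subject`,
#'   `condition`, or the path of a tab-delimited file with those columns.
#' @return a [paired_expression_set()].
#' @export
read_expression <- function(path, condition_map) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty expression file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  samples <- header[-1]
  n_field <- length(header)
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != n_field))
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 which(widths != n_field)[1] + 1L, n_field,
                 widths[widths != n_field][1]))
  gene_ids <- vapply(body, `[`, character(1), 1L)
  values <- matrix(NA_real_, nrow = length(body), ncol = length(samples))
  for (i in seq_along(body)) {
    cell <- body[[i]][-1]
    num <- suppressWarnings(as.numeric(cell))
    if (anyNA(num)) {
      j <- which(is.na(num))[1]
      stop(sprintf("non-numeric cell '%s' at gene '%s', sample '%s'",
                   cell[j], gene_ids[i], samples[j]))
    }
    values[i, ] <- num
  }
  rownames(values) <- gene_ids
  colnames(values) <- samples
  cm <- read_condition_map(condition_map)
  missing <- setdiff(samples, cm$sample)
  if (length(missing))
    stop("samples missing from the condition map: ",
         paste(missing, collapse = ", "))
  idx <- match(samples, cm$sample)
  paired_expression_set(values,
                        subject_ids = cm$subject[idx],
                        condition_labels = cm$condition[idx])
}

read_condition_map <- function(condition_map) {
  if (is.character(condition_map) && length(condition_map) == 1L) {
    condition_map <- utils::read.delim(condition_map,
                                       stringsAsFactors = FALSE)
  }
  need <- c("sample", "subject", "condition")
  if (!all(need %in% names(condition_map)))
    stop("condition map needs columns: ", paste(need, collapse = ", "))
  condition_map[need] <- lapply(condition_map[need], as.character)
  condition_map
}

#' Write a paired expression set as tab-delimited text
#'
#' Writes the matrix (gene identifiers in the first column, sample
#' identifiers in the header) and, next to it, a `<path>.conditions.tsv`
#' condition map so that [read_expression()] can restore the pairing.
#'
#' @param x a `PairedExpressionSet`.
#' @param path output path for the matrix.
#' @return invisibly, the path of the condition-map file.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "PairedExpressionSet"))
  samples <- sprintf("%s_%s", x$subject_ids, x$condition_labels)
  header <- paste(c("gene", samples), collapse = "\t")
  rows <- vapply(seq_along(x$gene_ids), function(i) {
    paste(c(x$gene_ids[i],
            format(x$values[i, ], digits = 17, trim = TRUE,
                   scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  map_path <- paste0(path, ".conditions.tsv")
  utils::write.table(data.frame(sample = samples,
                                subject = x$subject_ids,
                                condition = x$condition_labels),
                     map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(map_path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: set name, description, then tab-separated member gene
#' identifiers.  Member order is preserved; duplicate members within a set
#' are collapsed.
#'
#' @param path path to the GMT file.
#' @return an object of class `"GeneSetCollection"`: a named list of
#'   character vectors with a `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d fields; at least 3 required",
                   i, length(f)))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("GMT line %d ('%s') has no members", i, f[1]))
    if (f[1] %in% names(sets))
      stop("duplicate set name: ", f[1])
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (set members).
#' @param descriptions optional named character vector of set descriptions.
#' @return a `"GeneSetCollection"`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("set names must be present and unique")
    if (any(!lengths(sets)))
      stop("empty gene sets are not allowed")
    sets <- lapply(sets, function(s) unique(as.character(s)))
  }
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(sets, descriptions = descriptions[names(sets)],
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x), "sets")
  if (length(x))
    cat(", sizes", min(lengths(x)), "-", max(lengths(x)))
  cat("\n")
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a `"GeneSetCollection"`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    d <- desc[[nm]]; if (is.null(d) || is.na(d)) d <- ""
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Long tab-delimited format with columns `subject`, `measurement`, `pre`,
#' `post`.  The training-induced delta (post - pre) is derived.
#'
#' @param path path to the file.
#' @return a `"PhenotypeTable"`: a data frame with an added `delta` column.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  phenotype_table(df)
}

#' Construct a phenotype table
#'
#' @param df data frame with columns `subject`, `measurement`, `pre`, `post`.
#' @return a `"PhenotypeTable"` data frame with derived `delta = post - pre`.
#' @export
phenotype_table <- function(df) {
  need <- c("subject", "measurement", "pre", "post")
  if (!all(need %in% names(df)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  df$subject <- as.character(df$subject)
  df$measurement <- as.character(df$measurement)
  df$pre <- as.numeric(df$pre)
  df$post <- as.numeric(df$post)
  if (anyDuplicated(df[c("subject", "measurement")]))
    stop("duplicate (subject, measurement) rows in phenotype table")
  df$delta <- df$post - df$pre
  class(df) <- c("PhenotypeTable", "data.frame")
  df
}

#' Write a phenotype table as tab-delimited text
#' @param phenotypes a `"PhenotypeTable"`.
#' @param path output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes[c("subject", "measurement", "pre", "post")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantile normalization
#'
#' Forces all columns of a matrix onto the same empirical distribution: the
#' value at rank k in every column becomes the mean across columns of the
#' k-th smallest values, with ties within a column receiving the mean of
#' their tied target quantiles.  Delegates to [limma::normalizeQuantiles()].
#'
#' @param m numeric matrix with at least two columns.
#' @return normalized matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("matrix must be numeric")
  if (ncol(m) < 2L) {
    warning("single-column matrix: quantile normalization is the identity")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Elementwise log2 transform with offset
#'
#' @param m numeric matrix.
#' @param offset nonnegative shift added before taking log2.
#' @return `log2(m + offset)`.
#' @export
log2_transform <- function(m, offset = 0) {
  m <- as.matrix(m)
  shifted <- m + offset
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)
    lab <- apply(utils::head(bad, 5), 1, paste, collapse = ",")
    stop("nonpositive values after offset at cells (row,col): ",
         paste(lab, collapse = "; "))
  }
  log2(shifted)
}
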
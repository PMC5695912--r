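# Synthetic paired expression data with planted, recoverable structure:
# modules whose within-module correlation differs between the pre and post
# conditions, a hub regulator whose neighborhood rewires, gene sets
# overlapping the planted modules, and phenotypes driven linearly by
# baseline expression.  Every stage of the network pipeline can be
# validated against the ground truth these generators record.

#' Configuration for the synthetic paired-expression generator
#'
#' Genes in a module are driven by one latent factor per subject and
#' condition, with loading `sqrt(rho)` and unit total variance, so that the
#' expected pairwise correlation within the module equals `rho` in that
#' condition.  Latent factors are drawn independently per condition, so the
#' pre/post pairing induces no cross-condition structure unless configured.
#' Rewiring means `within_corr_pre != within_corr_post`; a negative target
#' is realised with alternating sign loadings (pair correlations of
#' magnitude `|rho|`, mixed sign), since a common factor cannot make all
#' pairs of more than two genes negatively correlated.
#'
#' @param n_genes total number of genes.
#' @param n_subjects number of subjects; each contributes one pre and one
#'   post sample.
#' @param modules list of module descriptors, each a list with elements
#'   `size`, `rewired` (flag), `within_corr_pre`, `within_corr_post`
#'   (targets in \[-1, 1\]).
#' @param hub_gene_neighbors_pre,hub_gene_neighbors_post number of genes
#'   correlated with the hub regulator in each condition (0/0 disables the
#'   hub).
#' @param hub_corr target correlation between the hub and its neighbors
#'   in the pre condition.
#' @param hub_corr_post target hub-neighbor correlation in the post
#'   condition; defaults to `-hub_corr`, i.e. the neighborhood's
#'   correlation flips sign after training, the strongest form of hub
#'   rewiring.
#' @param noise_sd overall scale of the expression values; correlations do
#'   not depend on it.
#' @param phenotype_specs list of phenotype descriptors, each a list with
#'   `name`, `n_driver_genes`, `effect_size`, `noise_sd`.
#' @param coupling optional list `(a, b, corr_pre, corr_post)` giving two
#'   module indices that share a latent factor, with the stated
#'   cross-module correlation per condition (sign flips allowed).
#' @param base_mean mean log2 expression level.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a validated list of class `"SyntheticConfig"`.
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_subjects = 40,
                             modules = replicate(5, list(
                               size = 30, rewired = TRUE,
                               within_corr_pre = 0.7,
                               within_corr_post = 0), simplify = FALSE),
                             hub_gene_neighbors_pre = 30,
                             hub_gene_neighbors_post = 30,
                             hub_corr = 0.6,
                             hub_corr_post = -hub_corr,
                             noise_sd = 1,
                             phenotype_specs = list(),
                             coupling = NULL,
                             base_mean = 8,
                             seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_subjects = as.integer(n_subjects),
              modules = modules,
              hub_gene_neighbors_pre = as.integer(hub_gene_neighbors_pre),
              hub_gene_neighbors_post = as.integer(hub_gene_neighbors_post),
              hub_corr = hub_corr,
              hub_corr_post = hub_corr_post,
              noise_sd = noise_sd,
              phenotype_specs = phenotype_specs,
              coupling = coupling,
              base_mean = base_mean,
              seed = as.integer(seed))
  class(cfg) <- "SyntheticConfig"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_subjects < 4L) stop("n_subjects must be at least 4")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  sizes <- vapply(cfg$modules, function(m) as.integer(m$size), integer(1))
  n_hub <- if (cfg$hub_gene_neighbors_pre > 0L ||
               cfg$hub_gene_neighbors_post > 0L) {
    1L + max(cfg$hub_gene_neighbors_pre, cfg$hub_gene_neighbors_post)
  } else 0L
  if (sum(sizes) + n_hub > cfg$n_genes)
    stop(sprintf(
      "module sizes (%d) plus hub block (%d) exceed n_genes (%d)",
      sum(sizes), n_hub, cfg$n_genes))
  for (m in cfg$modules) {
    if (abs(m$within_corr_pre) > 1 || abs(m$within_corr_post) > 1)
      stop("module correlation targets must lie in [-1, 1]")
  }
  if (abs(cfg$hub_corr) > 1 || abs(cfg$hub_corr_post) > 1)
    stop("hub_corr must lie in [-1, 1]")
  invisible(cfg)
}

# Simulate one condition's genes x subjects block for a module with target
# correlation rho.  `signs` realises negative targets pairwise.
simulate_module_block <- function(size, n_subjects, rho) {
  f <- rnorm(n_subjects)
  signs <- rep(1, size)
  if (rho < 0) {
    signs <- rep(c(1, -1), length.out = size)
    rho <- -rho
  }
  load <- sqrt(rho)
  resid <- sqrt(1 - rho)
  noise <- matrix(rnorm(size * n_subjects), size, n_subjects)
  (signs * load) %o% f + resid * noise
}

#' Generate a paired expression set with planted structure
#'
#' @param config a [synthetic_config()].
#' @return list with elements `expression` (a `PairedExpressionSet`) and
#'   `truth` (class `"SyntheticTruth"`): `module_of_gene` (0 = background),
#'   `hub_gene_id`, `hub_neighbors_pre`, `hub_neighbors_post`,
#'   `planted_sets`, `phenotype_drivers`, `background_genes`.
#' @export
generate_paired_expression <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  ng <- config$n_genes; ns <- config$n_subjects
  gene_ids <- sprintf("g%04d", seq_len(ng))
  subjects <- sprintf("s%02d", seq_len(ns))
  module_of_gene <- setNames(integer(ng), gene_ids)

  vals <- list(pre = matrix(0, ng, ns), post = matrix(0, ng, ns))
  pos <- 0L
  module_genes <- list()
  for (k in seq_along(config$modules)) {
    m <- config$modules[[k]]
    idx <- pos + seq_len(m$size)
    module_of_gene[idx] <- k
    module_genes[[k]] <- gene_ids[idx]
    pos <- pos + m$size
  }

  # couple two modules through a shared factor if requested
  coup <- config$coupling
  for (cond in c("pre", "post")) {
    shared <- if (!is.null(coup)) rnorm(ns) else NULL
    chi <- if (!is.null(coup))
      coup[[paste0("corr_", cond)]] else 0
    for (k in seq_along(config$modules)) {
      m <- config$modules[[k]]
      rho <- m[[paste0("within_corr_", cond)]]
      idx <- which(module_of_gene == k)
      if (!is.null(coup) && k %in% c(coup$a, coup$b) && chi != 0) {
        s <- if (k == coup$a) 1 else sign(chi)
        own <- max(rho - abs(chi), 0)
        f <- rnorm(ns)
        noise <- matrix(rnorm(length(idx) * ns), length(idx), ns)
        blk <- sqrt(own) * rep(1, length(idx)) %o% f +
          s * sqrt(abs(chi)) * rep(1, length(idx)) %o% shared +
          sqrt(max(1 - own - abs(chi), 0)) * noise
        vals[[cond]][idx, ] <- blk
      } else {
        vals[[cond]][idx, ] <- simulate_module_block(length(idx), ns, rho)
      }
    }
  }

  # hub regulator block
  hub_gene <- NULL; nb_pre <- character(0); nb_post <- character(0)
  n_nb <- max(config$hub_gene_neighbors_pre, config$hub_gene_neighbors_post)
  if (n_nb > 0L) {
    hub_idx <- pos + 1L
    nb_idx <- pos + 1L + seq_len(n_nb)
    pos <- pos + 1L + n_nb
    hub_gene <- gene_ids[hub_idx]
    nb_pre <- gene_ids[utils::head(nb_idx, config$hub_gene_neighbors_pre)]
    nb_post <- gene_ids[utils::head(nb_idx, config$hub_gene_neighbors_post)]
    for (cond in c("pre", "post")) {
      active <- if (cond == "pre") nb_pre else nb_post
      rho <- if (cond == "pre") config$hub_corr else config$hub_corr_post
      h <- rnorm(ns)
      blk_idx <- c(hub_idx, nb_idx)
      loads <- ifelse(gene_ids[blk_idx] %in% c(hub_gene, active),
                      sqrt(abs(rho)), 0)
      # a negative target flips the neighbor loadings only, so
      # corr(hub, neighbor) = rho while neighbors stay mutually positive
      signs <- ifelse(gene_ids[blk_idx] == hub_gene, 1, sign(rho))
      noise <- matrix(rnorm(length(blk_idx) * ns), length(blk_idx), ns)
      vals[[cond]][blk_idx, ] <- (signs * loads) %o% h +
        sqrt(1 - loads^2) * noise
    }
  }

  # independent background genes
  bg_idx <- if (pos < ng) (pos + 1L):ng else integer(0)
  for (cond in c("pre", "post"))
    vals[[cond]][bg_idx, ] <- matrix(rnorm(length(bg_idx) * ns),
                                     length(bg_idx), ns)

  values <- cbind(vals$pre, vals$post) * config$noise_sd + config$base_mean
  eset <- paired_expression_set(
    values,
    subject_ids = c(subjects, subjects),
    condition_labels = rep(c("pre", "post"), each = ns),
    gene_ids = gene_ids)

  planted_sets <- setNames(module_genes,
                           sprintf("module_%d", seq_along(module_genes)))
  if (!is.null(hub_gene))
    planted_sets[["hub_neighborhood"]] <- c(hub_gene,
                                            union(nb_pre, nb_post))

  # phenotype drivers: hub first (if any), then module genes
  drivers <- list()
  pool <- c(hub_gene, unlist(module_genes))
  for (spec in config$phenotype_specs) {
    nd <- spec$n_driver_genes
    dg <- utils::head(pool, nd)
    drivers[[spec$name]] <- list(genes = dg,
                                 coefficients = rep(spec$effect_size,
                                                    length(dg)),
                                 noise_sd = spec$noise_sd)
  }

  truth <- structure(list(module_of_gene = module_of_gene,
                          hub_gene_id = hub_gene,
                          hub_neighbors_pre = nb_pre,
                          hub_neighbors_post = nb_post,
                          planted_sets = planted_sets,
                          phenotype_drivers = drivers,
                          background_genes = gene_ids[bg_idx]),
                     class = "SyntheticTruth")
  list(expression = eset, truth = truth)
}

#' Generate phenotypes linearly driven by baseline expression
#'
#' Each phenotype's training-induced delta per subject is a linear
#' combination of the subject's baseline (pre) expression of the driver
#' genes, plus Gaussian noise; the table carries a pre value and
#' `post = pre + delta`.
#'
#' @param truth `"SyntheticTruth"` from [generate_paired_expression()].
#' @param eset the matching `PairedExpressionSet`.
#' @param config the [synthetic_config()] (its `seed`, offset by one, seeds
#'   the phenotype noise).
#' @return a `"PhenotypeTable"`.
#' @export
generate_phenotypes <- function(truth, eset, config) {
  set.seed(config$seed + 1L)
  pre <- condition_matrix(eset, "pre")
  out <- list()
  for (nm in names(truth$phenotype_drivers)) {
    d <- truth$phenotype_drivers[[nm]]
    missing <- setdiff(d$genes, rownames(pre))
    if (length(missing))
      stop("unknown phenotype driver gene: ",
           paste(missing, collapse = ", "))
    delta <- if (length(d$genes)) {
      as.numeric(crossprod(pre[d$genes, , drop = FALSE], d$coefficients))
    } else rep(0, ncol(pre))
    delta <- delta + rnorm(ncol(pre), sd = d$noise_sd)
    base <- rnorm(ncol(pre), mean = 100, sd = 10)
    out[[nm]] <- data.frame(subject = colnames(pre), measurement = nm,
                            pre = base, post = base + delta)
  }
  phenotype_table(do.call(rbind, c(out, list(make.row.names = FALSE))))
}

#' Generate a gene-set collection of planted and decoy sets
#'
#' Planted sets are copies of the planted modules (and the hub's pre
#' neighborhood when a hub exists); decoy sets are drawn uniformly without
#' replacement from the background genes.
#'
#' @param truth `"SyntheticTruth"`.
#' @param n_decoy_sets number of decoy sets.
#' @param set_size size of each decoy set.
#' @param seed integer seed.
#' @return a `"GeneSetCollection"`.
#' @export
generate_gene_sets <- function(truth, n_decoy_sets = 50, set_size = 30,
                               seed = 1) {
  set.seed(seed)
  bg <- truth$background_genes
  if (n_decoy_sets > 0 && set_size > length(bg))
    stop(sprintf("set_size (%d) exceeds the background universe (%d)",
                 set_size, length(bg)))
  sets <- truth$planted_sets
  for (i in seq_len(n_decoy_sets))
    sets[[sprintf("decoy_%02d", i)]] <- sample(bg, set_size)
  desc <- setNames(ifelse(grepl("^decoy", names(sets)),
                          "decoy set", "planted set"), names(sets))
  gene_set_collection(sets, desc)
}

#' Write the synthetic ground truth as structured key-value text
#' @param truth `"SyntheticTruth"`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  lines <- c(
    paste0("hub_gene\t", if (is.null(truth$hub_gene_id)) "" else
      truth$hub_gene_id),
    paste0("hub_neighbors_pre\t",
           paste(truth$hub_neighbors_pre, collapse = ",")),
    paste0("hub_neighbors_post\t",
           paste(truth$hub_neighbors_post, collapse = ",")),
    vapply(names(truth$module_of_gene), function(g)
      sprintf("module\t%s\t%d", g, truth$module_of_gene[[g]]),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}
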
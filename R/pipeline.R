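# Pipeline orchestration: one entry point that runs the stages
# (simulate, diffcoex, sam, integrate, seednet, capillary) from a
# plain-text YAML configuration, writes each stage's artifacts in the
# formats of the corresponding module, and records a manifest of files,
# parameters and seeds so that any run can be reproduced exactly.

default_run_config <- function() {
  list(
    output_dir = "corewire_out",
    seed = 1,
    simulate = list(n_genes = 500, n_subjects = 40, n_modules = 3,
                    module_size = 30, within_corr_pre = 0.7,
                    within_corr_post = 0, hub_neighbors_pre = 20,
                    hub_neighbors_post = 0, n_decoy_sets = 20,
                    set_size = 30, phenotype_effect = 1,
                    phenotype_noise_sd = 1),
    diffcoex = list(beta = 6, min_module_size = 10, cut_fraction = 0.99,
                    n_perm = 499, pair_fdr = 0.01, n_random = 1000,
                    dispersion_fdr = 0.10),
    sam = list(n_perm = 999, fdr = 0.05),
    integrate = list(fdr = 0.10, score_n_perm = 499, score_fdr = 0.10),
    seednet = list(corr_fdr = 0.05, enrich_fdr = 0.10),
    capillary = list()
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and validate a pipeline run configuration
#'
#' @param config path to a YAML file, or a list; missing entries fall
#'   back to package defaults.
#' @return validated configuration list of class `"RunConfig"`.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_run_config(), config)
  for (field in c("expression", "condition_map", "gene_sets",
                  "phenotypes")) {
    for (stage in c("diffcoex", "sam", "integrate", "seednet")) {
      p <- cfg[[stage]][[field]]
      if (!is.null(p) && !file.exists(p))
        stop(sprintf("config field %s.%s: file not found: %s",
                     stage, field, p))
    }
  }
  for (field in c("points", "fibers", "region")) {
    p <- cfg$capillary[[field]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("config field capillary.%s: file not found: %s",
                   field, p))
  }
  class(cfg) <- c("RunConfig", "list")
  cfg
}

pipeline_log <- function(manifest, stage, msg, seed = NULL) {
  line <- sprintf("[%s] %s%s", stage, msg,
                  if (!is.null(seed)) sprintf(" (seed=%d)", seed) else "")
  message(line)
  manifest$log <- c(manifest$log, line)
  manifest
}

resolve_expression <- function(cfg, stage) {
  path <- cfg[[stage]]$expression
  if (is.null(path))
    path <- file.path(cfg$output_dir, "expression.tsv")
  cmap <- cfg[[stage]]$condition_map
  if (is.null(cmap)) cmap <- paste0(path, ".conditions.tsv")
  if (!file.exists(path))
    stop(stage, ": no expression matrix; run the simulate stage or set ",
         stage, ".expression in the config")
  read_expression(path, cmap)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order.  `"simulate"` writes a
#' synthetic dataset (expression matrix + condition map, gene sets,
#' phenotypes, ground truth); `"diffcoex"` fits the differential
#' co-expression network, applies the gene-pair permutation filter and
#' the module-dispersion test, and writes module assignments and the
#' module graph; `"sam"` runs the paired SAM-style analysis;
#' `"integrate"` builds the regulator-pathway-phenotype graph and degree
#' table; `"seednet"` builds the pre and post seed-gene networks;
#' `"capillary"` computes the Voronoi-domain morphometry.  A manifest of
#' outputs, parameters and seeds is written as JSON; identical
#' configurations reproduce identical outputs.
#'
#' @param config path to a YAML config or a list (see
#'   [read_run_config()]).
#' @param stages character vector of stage names, or `"all"`.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), stages = "all") {
  cfg <- read_run_config(config)
  known <- c("simulate", "diffcoex", "sam", "integrate", "seednet",
             "capillary")
  if (identical(stages, "all")) {
    stages <- known
    if (is.null(cfg$capillary$points))
      stages <- setdiff(stages, "capillary")
  }
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "coRewire",
                   version = as.character(utils::packageVersion("coRewire")),
                   seed = cfg$seed, stages = list(), files = character(0),
                   log = character(0))
  add_files <- function(manifest, ...) {
    manifest$files <- c(manifest$files, unlist(list(...)))
    manifest
  }

  for (stage in stages) {
    manifest <- pipeline_log(manifest, stage, "started", seed = cfg$seed)
    if (stage == "simulate") {
      sc <- cfg$simulate
      scfg <- synthetic_config(
        n_genes = sc$n_genes, n_subjects = sc$n_subjects,
        modules = replicate(sc$n_modules, list(
          size = sc$module_size, rewired = TRUE,
          within_corr_pre = sc$within_corr_pre,
          within_corr_post = sc$within_corr_post), simplify = FALSE),
        hub_gene_neighbors_pre = sc$hub_neighbors_pre,
        hub_gene_neighbors_post = sc$hub_neighbors_post,
        phenotype_specs = list(list(name = "vo2max_delta",
                                    n_driver_genes = 1,
                                    effect_size = sc$phenotype_effect,
                                    noise_sd = sc$phenotype_noise_sd)),
        seed = cfg$seed)
      sim <- generate_paired_expression(scfg)
      expr_path <- file.path(out, "expression.tsv")
      write_expression(sim$expression, expr_path)
      write_truth(sim$truth, file.path(out, "truth.tsv"))
      sets <- generate_gene_sets(sim$truth, sc$n_decoy_sets, sc$set_size,
                                 seed = cfg$seed)
      write_gmt(sets, file.path(out, "gene_sets.gmt"))
      ph <- generate_phenotypes(sim$truth, sim$expression, scfg)
      write_phenotypes(ph, file.path(out, "phenotypes.tsv"))
      manifest <- add_files(manifest, expr_path,
                            paste0(expr_path, ".conditions.tsv"),
                            file.path(out, c("truth.tsv", "gene_sets.gmt",
                                             "phenotypes.tsv")))
      manifest$stages$simulate <- c(sc, list(seed = cfg$seed))
    } else if (stage == "diffcoex") {
      dc <- cfg$diffcoex
      eset <- resolve_expression(cfg, "diffcoex")
      fit <- diffcoex(eset, beta = dc$beta,
                      min_module_size = dc$min_module_size,
                      cut_fraction = dc$cut_fraction)
      flt <- filter_gene_pairs(eset, fit$partition, n_perm = dc$n_perm,
                               fdr_threshold = dc$pair_fdr,
                               seed = cfg$seed)
      part <- flt$partition
      write_modules(part, file.path(out, "modules.tsv"))
      if (max(part) >= 1) {
        disp <- dispersion_significance(eset, part,
                                        n_random = dc$n_random,
                                        fdr_threshold = dc$dispersion_fdr,
                                        seed = cfg$seed)
        utils::write.table(disp, file.path(out, "dispersion.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        g <- build_module_graph(part, disp)
        write_module_graph(g, file.path(out, "module_graph"))
        manifest <- add_files(manifest, file.path(out, c(
          "dispersion.tsv", "module_graph.graphml", "module_graph.sif",
          "module_graph.edge_attributes.tsv")))
      }
      manifest <- add_files(manifest, file.path(out, "modules.tsv"))
      manifest$stages$diffcoex <- c(dc, list(seed = cfg$seed))
    } else if (stage == "sam") {
      eset <- resolve_expression(cfg, "sam")
      res <- sam_paired(eset, n_perm = cfg$sam$n_perm,
                        fdr_threshold = cfg$sam$fdr, seed = cfg$seed)
      write_sam(res, file.path(out, "sam.tsv"))
      manifest <- add_files(manifest, file.path(out, "sam.tsv"))
      manifest$stages$sam <- c(cfg$sam, list(seed = cfg$seed))
    } else if (stage == "integrate") {
      it <- cfg$integrate
      eset <- resolve_expression(cfg, "integrate")
      sets_path <- it$gene_sets
      if (is.null(sets_path)) sets_path <- file.path(out, "gene_sets.gmt")
      collection <- read_gmt(sets_path)
      ph_path <- it$phenotypes
      if (is.null(ph_path)) ph_path <- file.path(out, "phenotypes.tsv")
      phenotypes <- read_phenotypes(ph_path)
      regulators <- it$regulators
      if (is.null(regulators)) regulators <- eset$gene_ids[1]
      path_edges <- list()
      for (reg in regulators) {
        sc <- regulator_diffcoex_scores(eset, reg,
                                        n_perm = it$score_n_perm,
                                        fdr_threshold = it$score_fdr,
                                        seed = cfg$seed)
        e <- suppressWarnings(
          regulator_pathway_edges(sc, collection, eset$gene_ids,
                                  fdr_threshold = it$fdr))
        if (nrow(e)) path_edges[[reg]] <- e
      }
      phe <- regulator_phenotype_edges(eset, phenotypes, regulators,
                                       fdr_threshold = it$fdr)
      g <- assemble_graph(c(path_edges, list(phe$edges)))
      write_integration_graph(g, file.path(out, "integration"))
      manifest <- add_files(manifest, file.path(out, c(
        "integration.graphml", "integration.degrees.tsv")))
      manifest$stages$integrate <- c(it[setdiff(names(it), "regulators")],
                                     list(seed = cfg$seed))
    } else if (stage == "seednet") {
      sn <- cfg$seednet
      eset <- resolve_expression(cfg, "seednet")
      sets_path <- sn$gene_sets
      if (is.null(sets_path)) sets_path <- file.path(out, "gene_sets.gmt")
      collection <- read_gmt(sets_path)
      seed_gene <- sn$seed_gene
      if (is.null(seed_gene)) seed_gene <- eset$gene_ids[1]
      rows <- list()
      for (cond in c("pre", "post")) {
        net <- seed_condition_network(eset, seed_gene, cond, collection,
                                      corr_fdr = sn$corr_fdr,
                                      enrich_fdr = sn$enrich_fdr)
        igraph::write_graph(net$graph,
                            file.path(out, sprintf("seednet_%s.graphml",
                                                   cond)),
                            format = "graphml")
        rows[[cond]] <- data.frame(condition = cond,
                                   seed_gene = seed_gene,
                                   n_correlated =
                                     length(net$significant_genes),
                                   degree = net$degree)
      }
      utils::write.table(do.call(rbind, rows),
                         file.path(out, "seednet_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest <- add_files(manifest, file.path(out, c(
        "seednet_pre.graphml", "seednet_post.graphml",
        "seednet_summary.tsv")))
      manifest$stages$seednet <- c(sn, list(seed = cfg$seed))
    } else if (stage == "capillary") {
      cp <- cfg$capillary
      if (is.null(cp$points) || is.null(cp$region))
        stop("capillary stage needs capillary.points and capillary.region")
      pts <- read_capillary_points(cp$points)
      region <- read_polygons(cp$region)[[1]]
      fibers <- if (!is.null(cp$fibers)) read_polygons(cp$fibers)
                else list()
      section <- capillary_section(pts, fibers, region)
      dom <- voronoi_domains(section)
      write_domain_summary(dom, file.path(out, "capillary"))
      manifest <- add_files(manifest, file.path(out, c(
        "capillary.summary.tsv", "capillary.domain_areas.tsv")))
      manifest$stages$capillary <- list()
    }
    manifest <- pipeline_log(manifest, stage, "completed")
    # manifest written after every stage so partial failures leave a
    # record of the stages that did complete
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(manifest)
}
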
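#' Pipeline run configuration
#'
#' Collects input paths and every stage parameter, with defaults matching
#' the full-scale compendium analysis: zero-count filter at 25% of samples,
#' DE filter padj < 0.05 in >= 3 comparisons, 1000 trees with sqrt candidate
#' rule, absolute edge threshold 0.00858, minimum module size 12,
#' second-order neighborhoods, and 10 random-removal iterations. Every stage
#' seed is derived deterministically from the single global seed.
#'
#' @param counts path to the count-matrix TSV.
#' @param samples path to the sample-sheet TSV.
#' @param outdir output directory (created if absent).
#' @param gmt optional GMT gene-set file; enrichment and perturbation are
#'   skipped (with a warning) when missing.
#' @param de_table optional precomputed DE TSV; bypasses the internal DE
#'   stage.
#' @param max_zero_fraction,de_alpha,min_comparisons preprocessing knobs.
#' @param n_trees,k_rule forest parameters.
#' @param min_weight,top_density edge threshold (exactly one non-NULL).
#' @param min_module_size,ward_k graph/clustering knobs.
#' @param seed_gene,neighborhood_order neighborhood extraction (skipped when
#'   `seed_gene` is NULL or absent from the network).
#' @param perturb_class chemical class for the leave-class-out analysis
#'   (NULL = skip).
#' @param perturb_iterations random-removal rounds (default 10).
#' @param seed global integer seed.
#' @return a `run_config` list.
#' @export
run_config <- function(counts, samples, outdir, gmt = NULL, de_table = NULL,
                       max_zero_fraction = 0.25, de_alpha = 0.05,
                       min_comparisons = 3, n_trees = 1000, k_rule = "sqrt",
                       min_weight = 0.00858, top_density = NULL,
                       min_module_size = 12, ward_k = 6, seed_gene = NULL,
                       neighborhood_order = 2, perturb_class = NULL,
                       perturb_iterations = 10, seed = 1L) {
  cfg <- as.list(environment())
  if (!is.null(top_density)) cfg$min_weight <- NULL
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file holds `run_config()` arguments by name; `overrides` (from a
#' command line `--set key=value`) replace file values.
#'
#' @param path .yaml/.yml or .json file.
#' @param overrides named list of replacement values.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path, overrides = list()) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> infer -> analyze -> enrich -> perturb on one
#' configuration, writes every intermediate artifact into the output
#' directory, and records parameters, seeds, input checksums, and per-stage
#' counts in `manifest.json`. Reruns with the same config and inputs are
#' bit-identical.
#'
#' @param config a [run_config()] object.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "coexpnet",
    version = as.character(utils::packageVersion("coexpnet")),
    parameters = config[setdiff(names(config), c("counts", "samples",
                                                 "gmt", "de_table"))],
    inputs = list(), stages = list(), outputs = character(0)
  )
  for (f in c("counts", "samples", "gmt", "de_table")) {
    if (!is.null(config[[f]]))
      manifest$inputs[[f]] <- list(path = config[[f]],
                                   md5 = unname(tools::md5sum(config[[f]])))
  }
  emit <- function(df, name) {
    p <- write_tsv(df, file.path(config$outdir, name))
    manifest$outputs <<- c(manifest$outputs, name)
    p
  }

  # --- preprocess -----------------------------------------------------
  counts <- read_counts(config$counts)
  sheet <- read_sample_sheet(config$samples)
  cm <- filter_low_expression(counts, config$max_zero_fraction)
  det <- if (!is.null(config$de_table)) {
    differential_expression(cm, sheet, method = "external_table",
                            external_path = config$de_table)
  } else {
    differential_expression(cm, sheet)
  }
  genes <- filter_de_genes(det, min_comparisons = config$min_comparisons,
                           alpha = config$de_alpha)
  if (length(genes) < 3)
    stop("preprocess: fewer than 3 genes survive the DE filter")
  fc <- build_fc_matrix(det, genes)
  wk <- min(config$ward_k, ncol(fc))
  clus <- ward_cluster_treatments(fc, k = wk)
  emit(det, "de_table.tsv")
  write_fc_matrix(fc, file.path(config$outdir, "fc_matrix.tsv"))
  manifest$outputs <- c(manifest$outputs, "fc_matrix.tsv")
  emit(data.frame(treatment = names(clus$clusters),
                  cluster = unname(clus$clusters)), "treatment_clusters.tsv")
  manifest$stages$preprocess <- list(
    genes_in = nrow(counts), genes_after_zero_filter = nrow(cm),
    genes_after_de_filter = length(genes), n_samples = ncol(counts),
    n_treatments = ncol(fc), ward_k = wk)

  # --- infer ----------------------------------------------------------
  w <- infer_weight_matrix(fc, n_trees = config$n_trees,
                           k_rule = config$k_rule,
                           seed = derive_seed(config$seed, 1L))
  write_weights_sparse(w, file.path(config$outdir, "weights.tsv"))
  manifest$outputs <- c(manifest$outputs, "weights.tsv")
  el <- threshold_edges(w, min_weight = config$min_weight,
                        top_density = config$top_density)
  emit(el, "edges.tsv")
  write_sif(el, file.path(config$outdir, "network.sif"))
  manifest$outputs <- c(manifest$outputs, "network.sif")
  manifest$stages$infer <- list(
    n_genes = nrow(w), threshold = attr(el, "threshold"),
    n_edges = attr(el, "n_edges"), n_nodes = attr(el, "n_nodes"))

  # --- analyze --------------------------------------------------------
  if (nrow(el) == 0) stop("analyze: the thresholded network is empty")
  net <- build_graph(el)
  main <- main_component(net)
  part <- detect_modules(main, min_size = config$min_module_size)
  cent <- centrality(main, partition = part)
  emit(part, "modules.tsv")
  emit(cent, "centrality.tsv")
  classes <- setdiff(unique(sheet$class), "control")
  resp <- lapply(classes, function(cl) {
    pr <- module_response_profile(part, det,
                                  treatments = unique(
                                    sheet$treatment[sheet$class == cl]))
    cbind(class = cl, pr$modules)
  })
  emit(do.call(rbind, resp), "module_response.tsv")
  manifest$stages$analyze <- list(
    main_component_nodes = igraph::vcount(main),
    main_component_edges = igraph::ecount(main),
    n_modules = length(attr(part, "sizes")),
    module_sizes = as.integer(attr(part, "sizes")))
  if (!is.null(config$seed_gene)) {
    if (config$seed_gene %in% igraph::V(main)$name) {
      nb <- neighborhood(main, config$seed_gene,
                         order = config$neighborhood_order)
      emit(nb$nodes, "neighborhood_nodes.tsv")
      sif_edges <- igraph::as_data_frame(nb$subgraph, what = "edges")
      write_sif(data.frame(regulator = sif_edges$from,
                           target = sif_edges$to),
                file.path(config$outdir, "neighborhood.sif"))
      manifest$outputs <- c(manifest$outputs, "neighborhood.sif")
      manifest$stages$neighborhood <- list(seed_gene = config$seed_gene,
                                           n_nodes = nb$n_nodes,
                                           n_edges = nb$n_edges)
    } else {
      warning("seed gene ", config$seed_gene,
              " is not in the main component; neighborhood skipped")
    }
  }

  # --- enrich ---------------------------------------------------------
  if (is.null(config$gmt)) {
    warning("no GMT supplied; enrichment and perturbation skipped")
  } else {
    gsc <- read_gmt(config$gmt, universe = genes)
    enr <- module_enrichment(gsc = gsc, partition = part)
    emit(enr, "enrichment.tsv")
    manifest$stages$enrich <- list(n_sets = length(gsc$sets),
                                   n_tests = nrow(enr),
                                   n_enriched = sum(enr$enriched))

    # --- perturb ------------------------------------------------------
    if (!is.null(config$perturb_class)) {
      red <- remove_samples(counts, sheet, mode = "class",
                            class_label = config$perturb_class)
      # match the random null to the number of removed *class* samples;
      # orphaned control groups dropped alongside are not counted
      n_removed <- sum(sheet$class == config$perturb_class)
      class_w <- coexpression_from_counts(
        red$counts, red$sheet, genes = genes, n_trees = config$n_trees,
        k_rule = config$k_rule, seed = derive_seed(config$seed, 2L),
        max_zero_fraction = config$max_zero_fraction,
        de_alpha = config$de_alpha, min_comparisons = config$min_comparisons)
      rand_w <- random_null_weight_matrix(
        counts, sheet, n_removed = n_removed,
        iterations = config$perturb_iterations, genes = genes,
        n_trees = config$n_trees, k_rule = config$k_rule,
        seed = derive_seed(config$seed, 3L),
        max_zero_fraction = config$max_zero_fraction,
        de_alpha = config$de_alpha, min_comparisons = config$min_comparisons)
      pert <- compare_class_vs_random(class_w, rand_w, gsc)
      emit(pert, "perturbation.tsv")
      manifest$stages$perturb <- list(class = config$perturb_class,
                                      n_removed = n_removed,
                                      iterations = config$perturb_iterations,
                                      n_sets = nrow(pert))
    }
  }

  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
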
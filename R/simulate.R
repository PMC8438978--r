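#' Simulation configuration for a synthetic chemical-exposure compendium
#'
#' Builds and validates the configuration of the negative-binomial count
#' simulator. The simulated world mirrors a multi-chemical zebrafish-style
#' compendium: each treatment has a matched vehicle-control group, treatments
#' belong to chemical classes, and every class induces one (or more) planted
#' co-expressed gene modules with a designated hub gene.
#'
#' Counts are NB-distributed with per-gene baseline mean
#' `exp(N(baseline_log_mean, baseline_log_sd^2))` and variance
#' `mu + dispersion * mu^2`. For a treatment `t` of class `c`, every gene `g`
#' in a module planted for `c` has its mean multiplied by `2^(beta_gt)` with
#' `beta_gt = effect_size_log2 * f_t * m_g`: the latent factor
#' `f_t ~ N(1, effect_sd_log2^2)` is shared by all genes of the module, which
#' is what makes the module co-expressed across treatments, and the per-gene
#' multiplier `m_g` is Uniform(0.5, 1) except for hub genes, which get
#' `m_g = 1` (the strongest, most consistent responders).
#'
#' @param n_genes number of genes.
#' @param n_classes number of chemical classes with planted modules.
#' @param treatments_per_class treatments in each class.
#' @param n_other_treatments unclassed treatments with no planted response.
#' @param replicates_per_treatment replicates per treated and per control
#'   group (3-8 in the emulated study; must be >= 2).
#' @param module_sizes planted module sizes: a numeric vector with one module
#'   per class, or a list of length `n_classes` with one vector of sizes per
#'   class.
#' @param hub_per_module if TRUE the first gene of each module is a hub.
#' @param effect_size_log2 mean planted induction on the log2 scale.
#' @param effect_sd_log2 SD of the shared per-treatment latent factor.
#' @param dispersion NB dispersion alpha (variance mu + alpha mu^2).
#' @param baseline_log_mean,baseline_log_sd natural-log mean/SD of baselines.
#' @param noise_corr in `[0, 1)`; strength of a shared per-sample log2
#'   disturbance applied to all genes (0 = independent samples).
#' @param class_labels optional class names; defaults to FRC,
#'   AHR2_Activator, then class3, class4, ...
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300L,
                       n_classes = 2L,
                       treatments_per_class = 8L,
                       n_other_treatments = 4L,
                       replicates_per_treatment = 4L,
                       module_sizes = c(40L, 40L),
                       hub_per_module = TRUE,
                       effect_size_log2 = 2,
                       effect_sd_log2 = 0.3,
                       dispersion = 0.05,
                       baseline_log_mean = 5.5,
                       baseline_log_sd = 1,
                       noise_corr = 0,
                       class_labels = NULL,
                       seed = 1L) {
  if (is.numeric(module_sizes) && !is.list(module_sizes)) {
    if (length(module_sizes) != n_classes)
      stop("numeric 'module_sizes' must have one entry per class")
    module_sizes <- as.list(as.integer(module_sizes))
  }
  if (length(module_sizes) != n_classes)
    stop("'module_sizes' must have length n_classes")
  module_sizes <- lapply(module_sizes, as.integer)
  if (any(unlist(module_sizes) < 1))
    stop("module sizes must be >= 1")
  if (sum(unlist(module_sizes)) > n_genes)
    stop("planted module genes exceed n_genes")
  if (replicates_per_treatment < 2)
    stop("replicates_per_treatment must be >= 2")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (baseline_log_sd <= 0) stop("baseline_log_sd must be > 0")
  if (effect_size_log2 < 0) stop("effect_size_log2 must be >= 0")
  if (effect_sd_log2 < 0) stop("effect_sd_log2 must be >= 0")
  if (noise_corr < 0 || noise_corr >= 1) stop("noise_corr must be in [0, 1)")
  if (is.null(class_labels)) {
    class_labels <- c("FRC", "AHR2_Activator",
                      if (n_classes > 2) paste0("class", seq(3, n_classes)))
    class_labels <- class_labels[seq_len(n_classes)]
  }
  if (length(class_labels) != n_classes)
    stop("'class_labels' must have length n_classes")
  structure(list(
    n_genes = as.integer(n_genes),
    n_classes = as.integer(n_classes),
    treatments_per_class = as.integer(treatments_per_class),
    n_other_treatments = as.integer(n_other_treatments),
    replicates_per_treatment = as.integer(replicates_per_treatment),
    module_sizes = module_sizes,
    hub_per_module = isTRUE(hub_per_module),
    effect_size_log2 = effect_size_log2,
    effect_sd_log2 = effect_sd_log2,
    dispersion = dispersion,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    noise_corr = noise_corr,
    class_labels = class_labels,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic count compendium with planted module structure
#'
#' Draws a gene-by-sample count matrix, the matching sample sheet, and the
#' ground truth used by validation tests (planted module membership, hub
#' genes, per-(gene, treatment) planted log2 fold changes, and the
#' treatment-to-control pairing).
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `counts` (integer matrix, genes x samples),
#'   `samples` (data.frame: sample, treatment, control_for, class,
#'   replicate), and `truth` (list: module_membership, class_of_module,
#'   hub_genes, planted_lfc, control_pairing).
#' @export
generate_compendium <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  genes <- sprintf("g%04d", seq_len(config$n_genes))

  # planted modules: contiguous blocks of genes, one hub each (first gene)
  module_membership <- rep(NA_integer_, config$n_genes)
  names(module_membership) <- genes
  class_of_module <- character(0)
  hub_genes <- character(0)
  nxt <- 1L
  mod_id <- 0L
  for (ci in seq_len(config$n_classes)) {
    for (sz in config$module_sizes[[ci]]) {
      mod_id <- mod_id + 1L
      idx <- seq(nxt, nxt + sz - 1L)
      module_membership[idx] <- mod_id
      class_of_module[as.character(mod_id)] <- config$class_labels[ci]
      if (config$hub_per_module) hub_genes <- c(hub_genes, genes[idx[1]])
      nxt <- nxt + sz
    }
  }

  # treatments and matched vehicle controls
  trt <- character(0)
  trt_class <- character(0)
  for (ci in seq_len(config$n_classes)) {
    lab <- config$class_labels[ci]
    ids <- sprintf("%s_T%02d", lab, seq_len(config$treatments_per_class))
    trt <- c(trt, ids)
    trt_class <- c(trt_class, rep(lab, length(ids)))
  }
  if (config$n_other_treatments > 0) {
    ids <- sprintf("other_T%02d", seq_len(config$n_other_treatments))
    trt <- c(trt, ids)
    trt_class <- c(trt_class, rep("other", length(ids)))
  }
  names(trt_class) <- trt
  ctrl_of <- setNames(paste0(trt, "_ctrl"), trt)

  # latent draws (fixed order => deterministic given seed)
  baseline <- exp(rnorm(config$n_genes, config$baseline_log_mean,
                        config$baseline_log_sd))
  m_g <- runif(config$n_genes, 0.5, 1)
  m_g[genes %in% hub_genes] <- 1
  f_t <- setNames(rnorm(length(trt), 1, config$effect_sd_log2), trt)

  # planted log2FC: nonzero only for genes in a module of the treatment class
  planted_lfc <- matrix(0, config$n_genes, length(trt),
                        dimnames = list(genes, trt))
  for (t in trt) {
    responding <- !is.na(module_membership) &
      class_of_module[as.character(module_membership)] == trt_class[t]
    if (any(responding)) {
      planted_lfc[responding, t] <-
        config$effect_size_log2 * f_t[t] * m_g[responding]
    }
  }

  nrep <- config$replicates_per_treatment
  sample_rows <- list()
  count_cols <- list()
  size <- 1 / config$dispersion
  draw_group <- function(mu_vec, n) {
    sapply(seq_len(n), function(i) {
      mu <- mu_vec
      if (config$noise_corr > 0)
        mu <- mu * 2^(config$noise_corr * rnorm(1))
      rnbinom(length(mu), size = size, mu = mu)
    })
  }
  for (t in trt) {
    mu_trt <- baseline * 2^planted_lfc[, t]
    ctr <- ctrl_of[[t]]
    cm_c <- draw_group(baseline, nrep)
    colnames(cm_c) <- sprintf("%s_r%d", ctr, seq_len(nrep))
    cm_t <- draw_group(mu_trt, nrep)
    colnames(cm_t) <- sprintf("%s_r%d", t, seq_len(nrep))
    count_cols[[length(count_cols) + 1L]] <- cbind(cm_c, cm_t)
    sample_rows[[length(sample_rows) + 1L]] <- data.frame(
      sample = c(colnames(cm_c), colnames(cm_t)),
      treatment = c(rep(ctr, nrep), rep(t, nrep)),
      control_for = c(rep("", nrep), rep(ctr, nrep)),
      class = c(rep("control", nrep), rep(trt_class[[t]], nrep)),
      replicate = c(seq_len(nrep), seq_len(nrep)),
      stringsAsFactors = FALSE
    )
  }
  counts <- do.call(cbind, count_cols)
  storage.mode(counts) <- "integer"
  rownames(counts) <- genes
  samples <- do.call(rbind, sample_rows)
  rownames(samples) <- NULL

  truth <- list(
    module_membership = module_membership,
    class_of_module = class_of_module,
    hub_genes = hub_genes,
    planted_lfc = planted_lfc,
    control_pairing = ctrl_of,
    gene_multiplier = setNames(m_g, genes),
    treatment_factor = f_t
  )
  list(counts = counts, samples = samples, truth = truth)
}

#' Write simulator ground truth as JSON
#'
#' @param truth the `truth` element of [generate_compendium()] output.
#' @param path output path.
#' @export
write_sim_truth <- function(truth, path) {
  out <- truth
  out$planted_lfc <- list(
    genes = rownames(truth$planted_lfc),
    treatments = colnames(truth$planted_lfc),
    lfc = unname(apply(truth$planted_lfc, 1, as.numeric, simplify = FALSE))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
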
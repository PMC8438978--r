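# Shared synthetic fixtures, built in code at test time.

# Small compendium used by several files; cached per session.
small_compendium <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 120, n_classes = 2, treatments_per_class = 6,
                        n_other_treatments = 2, module_sizes = c(25L, 25L),
                        seed = 101)
      cache <<- generate_compendium(cfg)
    }
    cache
  }
})

# Hand-buildable sample sheet: one control group per treatment, nrep each.
toy_sheet <- function(treatments, classes, nrep = 3) {
  do.call(rbind, lapply(seq_along(treatments), function(i) {
    t <- treatments[i]; ctr <- paste0(t, "_ctrl")
    data.frame(
      sample = c(sprintf("%s_r%d", ctr, 1:nrep), sprintf("%s_r%d", t, 1:nrep)),
      treatment = c(rep(ctr, nrep), rep(t, nrep)),
      control_for = c(rep("", nrep), rep(ctr, nrep)),
      class = c(rep("control", nrep), rep(classes[i], nrep)),
      replicate = c(1:nrep, 1:nrep), stringsAsFactors = FALSE)
  }))
}

# DE table with given per-(gene, treatment) values.
toy_de <- function(genes, treatments, log2fc, p = NULL, padj = NULL) {
  grid <- expand.grid(gene = genes, treatment = treatments,
                      stringsAsFactors = FALSE)
  attr(grid, "out.attrs") <- NULL
  grid$log2fc <- log2fc
  grid$p <- if (is.null(p)) rep(0.5, nrow(grid)) else p
  grid$padj <- if (is.null(padj)) grid$p else padj
  grid
}

# Per-gene observed log2 ratios (treated vs matched control group means),
# computed directly from counts -- independent of the DE machinery.
observed_log2_ratio <- function(counts, sheet, treatment) {
  ctrl <- unique(sheet$control_for[sheet$treatment == treatment])
  st <- sheet$sample[sheet$treatment == treatment]
  sc <- sheet$sample[sheet$treatment == ctrl]
  log2((rowMeans(counts[, st, drop = FALSE]) + 0.5) /
         (rowMeans(counts[, sc, drop = FALSE]) + 0.5))
}
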
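#' Remove samples by chemical class or at random
#'
#' Class mode removes every sample whose sheet class equals `class_label`
#' (vehicle controls carry class "control" and are never removed directly).
#' Random mode removes `n_removed` non-control samples uniformly without
#' replacement, reproducibly given `seed`. Afterwards, any treatment left
#' with fewer than 2 treated replicates, or whose matched control group was
#' left with fewer than 2 replicates, is dropped entirely (its remaining
#' samples removed); control groups serving no surviving treatment are
#' dropped too. Dropped treatments are reported in the `dropped_treatments`
#' attribute.
#'
#' @param counts genes x samples count matrix.
#' @param sheet sample sheet.
#' @param mode "class" or "random".
#' @param class_label chemical class to remove (class mode).
#' @param n_removed number of units to remove (random mode).
#' @param seed integer seed (random mode).
#' @param unit random-removal unit: individual "sample"s (default) or whole
#'   "treatment"s (all treated samples of `n_removed` random treatments) —
#'   the alternative reading of the published removal procedure.
#' @return list (counts, sheet) restricted to surviving samples.
#' @export
remove_samples <- function(counts, sheet, mode = c("class", "random"),
                           class_label = NULL, n_removed = NULL, seed = NULL,
                           unit = c("sample", "treatment")) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  validate_sample_sheet(sheet)
  if (mode == "class") {
    if (is.null(class_label) || !class_label %in% sheet$class)
      stop("unknown or missing class_label")
    out <- sheet$sample[sheet$class == class_label]
  } else if (unit == "treatment") {
    stopifnot(!is.null(n_removed))
    pool <- unique(sheet$treatment[sheet$class != "control"])
    if (n_removed >= length(pool)) stop("n_removed must leave a treatment")
    if (!is.null(seed)) set.seed(seed)
    victims <- sample(pool, n_removed)
    out <- sheet$sample[sheet$treatment %in% victims]
  } else {
    stopifnot(!is.null(n_removed))
    pool <- sheet$sample[sheet$class != "control"]
    if (n_removed >= nrow(sheet)) stop("n_removed must be < total samples")
    if (n_removed > length(pool)) stop("n_removed exceeds non-control samples")
    if (!is.null(seed)) set.seed(seed)
    out <- sample(pool, n_removed)
  }
  keep <- !(sheet$sample %in% out)
  sh <- sheet[keep, , drop = FALSE]

  # drop treatments broken by the removal
  ctrl_of <- treatment_controls(sheet)
  nrep <- table(sh$treatment)
  dropped <- character(0)
  for (t in names(ctrl_of)) {
    nt <- if (t %in% names(nrep)) nrep[[t]] else 0L
    ncl <- if (ctrl_of[[t]] %in% names(nrep)) nrep[[ctrl_of[[t]]]] else 0L
    if (nt < 2 || ncl < 2) dropped <- c(dropped, t)
  }
  if (length(dropped)) {
    message("dropping treatment(s) left without enough replicates: ",
            paste(dropped, collapse = ", "))
    sh <- sh[!sh$treatment %in% dropped, , drop = FALSE]
  }
  surviving_ctrls <- unique(ctrl_of[setdiff(names(ctrl_of), dropped)])
  orphan <- sh$class == "control" & !sh$treatment %in% surviving_ctrls
  sh <- sh[!orphan, , drop = FALSE]
  rownames(sh) <- NULL
  res <- list(counts = counts[, sh$sample, drop = FALSE], sheet = sh)
  attr(res, "dropped_treatments") <- dropped
  res
}

# Full counts -> weight-matrix path shared by the perturbation stages.
# If `genes` is NULL the DE-based gene filter is re-applied to the reduced
# data; otherwise the weight matrix is inferred on the fixed gene set.
coexpression_from_counts <- function(counts, sheet, genes = NULL,
                                     n_trees = 1000, k_rule = "sqrt",
                                     seed = 42L, max_zero_fraction = 0.25,
                                     de_alpha = 0.05, min_comparisons = 3) {
  cm <- filter_low_expression(counts, max_zero_fraction)
  det <- differential_expression(cm, sheet)
  if (is.null(genes)) {
    genes <- filter_de_genes(det, min_comparisons = min_comparisons,
                             alpha = de_alpha)
  } else {
    genes <- intersect(genes, rownames(cm))
  }
  if (length(genes) < 2) stop("fewer than 2 genes available for inference")
  fc <- build_fc_matrix(det, genes)
  fc <- standardize_profiles(fc)
  infer_weight_matrix(fc, n_trees = n_trees, k_rule = k_rule, seed = seed,
                      standardize = FALSE)
}

#' Averaged weight matrix under random sample removal
#'
#' For each of `iterations` rounds, removes `n_removed` random non-control
#' samples, recomputes differential expression and the fold-change matrix on
#' the surviving treatments, infers a weight matrix, and finally averages
#' the matrices elementwise. When gene sets differ between rounds (the DE
#' filter is re-applied unless `genes` is fixed), each gene pair is averaged
#' over the rounds in which both genes were present.
#'
#' @param counts genes x samples count matrix.
#' @param sheet sample sheet.
#' @param n_removed samples removed per round.
#' @param iterations number of rounds (default 10: the first removal plus
#'   nine repeats).
#' @param seed integer seed; each round's removal and forest are seeded from
#'   it deterministically.
#' @param genes optional fixed gene set for inference (recommended when the
#'   result will be compared with a class-removal matrix).
#' @param n_trees,k_rule forest parameters, see [infer_weight_matrix()].
#' @param unit removal unit per round, see [remove_samples()].
#' @param ... further arguments for the preprocessing stage.
#' @return the averaged weight matrix; the per-round matrices are attached
#'   as the `iteration_weights` attribute.
#' @export
random_null_weight_matrix <- function(counts, sheet, n_removed,
                                      iterations = 10, seed = 1L,
                                      genes = NULL, n_trees = 1000,
                                      k_rule = "sqrt", unit = "sample", ...) {
  stopifnot(iterations >= 1)
  ws <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    red <- remove_samples(counts, sheet, mode = "random",
                          n_removed = n_removed, unit = unit,
                          seed = derive_seed(seed, 1000L + it))
    ws[[it]] <- coexpression_from_counts(red$counts, red$sheet, genes = genes,
                                         n_trees = n_trees, k_rule = k_rule,
                                         seed = derive_seed(seed, 2000L + it),
                                         ...)
  }
  avg <- average_weights(ws)
  attr(avg, "iteration_weights") <- ws
  avg
}

# Elementwise mean of weight matrices over the union gene set; each gene
# pair is averaged over the matrices in which both genes are present.
average_weights <- function(ws) {
  all_genes <- sort(unique(unlist(lapply(ws, rownames))))
  if (length(all_genes) < 2) stop("common gene set is empty")
  acc <- matrix(0, length(all_genes), length(all_genes),
                dimnames = list(all_genes, all_genes))
  cnt <- acc
  for (w in ws) {
    g <- rownames(w)
    acc[g, g] <- acc[g, g] + w
    cnt[g, g] <- cnt[g, g] + 1
  }
  avg <- acc / pmax(cnt, 1)
  avg[cnt == 0] <- NA_real_
  diag(avg) <- 0
  avg
}

#' Mean co-expression of a gene set
#'
#' Mean of the (unthresholded) weight-matrix entries over all ordered pairs
#' of distinct genes of the set that are present in the matrix.
#'
#' @param w weight matrix.
#' @param genes gene ids of the set.
#' @param symmetric average `w` with its transpose first (default FALSE).
#' @return the mean weight, or `NA` (with a message) when fewer than 2 set
#'   genes are present.
#' @export
set_mean_coexpression <- function(w, genes, symmetric = FALSE) {
  present <- intersect(unique(genes), rownames(w))
  if (length(present) < 2) {
    message("fewer than 2 set genes present in the weight matrix; skipped")
    return(NA_real_)
  }
  if (symmetric) w <- (w + t(w)) / 2
  sub <- w[present, present]
  mean(sub[row(sub) != col(sub)], na.rm = TRUE)
}

#' Compare class-removed and random-removed co-expression per gene set
#'
#' For every gene set, computes the mean co-expression in the class-removed
#' weight matrix and in the averaged random-removal matrix; `delta` is class
#' minus random, with direction "lower" (the set's genes are less tightly
#' co-expressed without the class, i.e. the class drives them) or "higher".
#' When the per-round random matrices are supplied, an empirical rank - the
#' fraction of rounds whose set mean lies below the class-removed mean - is
#' added as an uncertainty measure (an extension beyond the original
#' procedure, reported in its own column).
#'
#' @param class_w weight matrix inferred after removing one chemical class.
#' @param random_avg_w averaged random-removal matrix
#'   ([random_null_weight_matrix()]).
#' @param gsc gene-set collection from [read_gmt()].
#' @param random_iteration_ws optional list of per-round matrices (defaults
#'   to the `iteration_weights` attribute of `random_avg_w`).
#' @param symmetric see [set_mean_coexpression()].
#' @return data.frame (set, n_genes_used, mean_class_removed,
#'   mean_random_avg, delta, direction, empirical_rank), sorted by |delta|
#'   decreasing. Sets with fewer than 2 usable genes are skipped.
#' @export
compare_class_vs_random <- function(class_w, random_avg_w, gsc,
                                    random_iteration_ws = NULL,
                                    symmetric = FALSE) {
  if (is.null(random_iteration_ws))
    random_iteration_ws <- attr(random_avg_w, "iteration_weights")
  rows <- lapply(names(gsc$sets), function(nm) {
    set <- gsc$sets[[nm]]
    used <- length(intersect(set, intersect(rownames(class_w),
                                            rownames(random_avg_w))))
    mc <- suppressMessages(set_mean_coexpression(class_w, set, symmetric))
    mr <- suppressMessages(set_mean_coexpression(random_avg_w, set, symmetric))
    if (is.na(mc) || is.na(mr)) return(NULL)
    delta <- mc - mr
    er <- NA_real_
    if (!is.null(random_iteration_ws)) {
      its <- vapply(random_iteration_ws, function(wi) {
        suppressMessages(set_mean_coexpression(wi, set, symmetric))
      }, numeric(1))
      if (all(is.na(its))) er <- NA_real_
      else er <- mean(its < mc, na.rm = TRUE)
    }
    data.frame(set = nm, n_genes_used = used, mean_class_removed = mc,
               mean_random_avg = mr, delta = delta,
               direction = if (delta < 0) "lower" else "higher",
               empirical_rank = er, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set had 2 or more usable genes")
  out <- out[order(-abs(out$delta), out$set), ]
  rownames(out) <- NULL
  out
}
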
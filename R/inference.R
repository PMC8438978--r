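#' Standardize fold-change profiles
#'
#' Centers and scales each gene row of the log2FC matrix to mean 0 and unit
#' (sample) variance, so that random-forest importances are on a comparable
#' scale across targets. Rows with zero variance are dropped with a warning.
#'
#' @param fc genes x treatments matrix.
#' @return standardized matrix (possibly with fewer rows).
#' @export
standardize_profiles <- function(fc) {
  stopifnot(ncol(fc) >= 2)
  s <- apply(fc, 1, sd)
  drop <- s == 0 | !is.finite(s)
  if (any(drop)) {
    warning(sum(drop), " constant profile(s) dropped before inference")
    fc <- fc[!drop, , drop = FALSE]
    s <- s[!drop]
  }
  (fc - rowMeans(fc)) / s
}

resolve_mtry <- function(k_rule, p) {
  if (is.numeric(k_rule)) return(max(1L, min(as.integer(k_rule), p)))
  switch(match.arg(k_rule, c("sqrt", "all")),
         sqrt = max(1L, as.integer(floor(sqrt(p)))),
         all = as.integer(p))
}

#' Random-forest importance of predictor genes for one target
#'
#' Fits an ensemble of CART regression trees predicting the target profile
#' from the predictor profiles and returns, per predictor, the mean over
#' trees of the total variance reduction at nodes splitting on it, divided
#' by the number of observations. Trees are fully grown (minimum leaf size
#' 1) on bootstrap samples, with `k_rule` candidate predictors per split and
#' split ties broken by the candidate drawn first.
#'
#' @param target_profile numeric vector of length n_observations.
#' @param predictor_profiles predictors x observations matrix.
#' @param n_trees trees in the ensemble (default 1000).
#' @param k_rule "sqrt" (floor(sqrt(p)) candidates per split, the default),
#'   "all", or an integer.
#' @param seed optional integer seed (set just before fitting).
#' @param max_depth maximum tree depth; `Inf` (default) grows to purity.
#'   `max_depth = 1` gives decision stumps, useful for oracle checks.
#' @param bootstrap grow each tree on a bootstrap resample (default TRUE).
#' @return named non-negative numeric vector, one importance per predictor.
#' @export
target_importances <- function(target_profile, predictor_profiles,
                               n_trees = 1000, k_rule = "sqrt", seed = NULL,
                               max_depth = Inf, bootstrap = TRUE) {
  X <- t(predictor_profiles)
  if (nrow(X) < 3) stop("at least 3 observations are required")
  if (length(target_profile) != nrow(X))
    stop("target and predictors disagree on the number of observations")
  if (!is.null(seed)) set.seed(seed)
  md <- if (is.finite(max_depth)) as.integer(max_depth) else 0L
  imp <- .rf_importance(X, as.numeric(target_profile), as.integer(n_trees),
                        resolve_mtry(k_rule, ncol(X)), md, isTRUE(bootstrap))
  names(imp) <- rownames(predictor_profiles)
  imp
}

#' Infer the directed co-expression weight matrix
#'
#' Runs [target_importances()] once per gene, using all other genes as
#' candidate predictors (no pre-selection of regulators or targets), and
#' assembles the regulator x target weight matrix `w[j, i]` = importance of
#' gene j for predicting gene i. Each target's forest is seeded from the
#' global seed and a hash of the target's gene id, so results are
#' independent of the order in which targets are processed (serial,
#' per-target-parallel, and gene-permuted runs agree).
#'
#' @param fc genes x treatments log2FC matrix.
#' @param n_trees trees per target ensemble (default 1000).
#' @param k_rule candidate-predictor rule, see [target_importances()].
#' @param seed global integer seed (default 42).
#' @param standardize standardize profiles first (default TRUE).
#' @return regulator x target weight matrix with zero diagonal and an
#'   `inference_params` attribute.
#' @export
infer_weight_matrix <- function(fc, n_trees = 1000, k_rule = "sqrt",
                                seed = 42L, standardize = TRUE) {
  stopifnot(ncol(fc) >= 3)
  if (standardize) fc <- standardize_profiles(fc)
  genes <- rownames(fc)
  n <- length(genes)
  if (n < 2) stop("need at least 2 genes to infer a network")
  # canonical (sorted) gene order inside the forests, so the result is
  # exactly equivariant under permutations of the input gene order
  ord <- order(genes)
  fcs <- fc[ord, , drop = FALSE]
  gs <- genes[ord]
  w <- matrix(0, n, n, dimnames = list(gs, gs))
  for (i in seq_len(n)) {
    imp <- target_importances(fcs[i, ], fcs[-i, , drop = FALSE],
                              n_trees = n_trees, k_rule = k_rule,
                              seed = derive_seed(seed, name_hash(gs[i])))
    w[-i, i] <- imp
  }
  w <- w[genes, genes]
  attr(w, "inference_params") <- list(n_trees = n_trees, k_rule = k_rule,
                                      seed = seed)
  w
}

#' Threshold a weight matrix into a directed edge list
#'
#' Keeps directed edges with weight at or above `min_weight`, or, in
#' density mode, the strongest edges down to a target edge density
#' (`edges / (n * (n - 1))`). Exactly one of the two must be given. The
#' absolute threshold is dataset-specific (it was tuned on the full-scale
#' compendium to give a network with usable structure); density mode is the
#' portable alternative for smaller or synthetic data.
#'
#' @param w regulator x target weight matrix.
#' @param min_weight absolute weight threshold (e.g. 0.00858).
#' @param top_density target edge density in (0, 1].
#' @return data.frame (regulator, target, weight) sorted by decreasing
#'   weight, with attributes `threshold`, `n_nodes`, `n_edges`.
#' @export
threshold_edges <- function(w, min_weight = NULL, top_density = NULL) {
  if (is.null(min_weight) == is.null(top_density))
    stop("give exactly one of 'min_weight' or 'top_density'")
  diag(w) <- 0
  idx <- which(row(w) != col(w), arr.ind = TRUE)
  el <- data.frame(regulator = rownames(w)[idx[, 1]],
                   target = colnames(w)[idx[, 2]],
                   weight = w[idx], stringsAsFactors = FALSE)
  el <- el[order(-el$weight, el$regulator, el$target), ]
  if (!is.null(min_weight)) {
    el <- el[el$weight >= min_weight, , drop = FALSE]
    thr <- min_weight
  } else {
    stopifnot(top_density > 0, top_density <= 1)
    n_keep <- min(nrow(el), ceiling(top_density * nrow(w) * (nrow(w) - 1)))
    el <- el[seq_len(n_keep), , drop = FALSE]
    thr <- if (n_keep > 0) el$weight[n_keep] else Inf
  }
  rownames(el) <- NULL
  if (nrow(el) == 0) warning("threshold yields an empty network")
  attr(el, "threshold") <- thr
  attr(el, "n_nodes") <- length(unique(c(el$regulator, el$target)))
  attr(el, "n_edges") <- nrow(el)
  el
}
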
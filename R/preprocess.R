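#' Remove low-expression genes
#'
#' A gene is removed when its number of zero-count samples reaches
#' `ceiling(max_zero_fraction * n_samples)`. With 170 samples and the default
#' fraction 0.25 the boundary is 43 zeros: a gene with 43 or more zeros is
#' dropped, one with 42 is kept.
#'
#' @param counts genes x samples count matrix.
#' @param max_zero_fraction fraction of zero samples at which a gene is
#'   removed (default 0.25).
#' @return the count matrix restricted to surviving genes, original order.
#' @export
filter_low_expression <- function(counts, max_zero_fraction = 0.25) {
  stopifnot(max_zero_fraction > 0, max_zero_fraction <= 1)
  boundary <- ceiling(max_zero_fraction * ncol(counts))
  nzero <- rowSums(counts == 0)
  keep <- nzero < boundary
  if (!any(keep)) warning("low-expression filter removed every gene")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio of the gene's count to its geometric mean over samples; genes
#' whose geometric mean is zero (any zero count) are excluded from the
#' median.
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  logg <- rowMeans(log(counts))           # -Inf for genes with any zero
  use <- is.finite(logg)
  if (!any(use))
    stop("no gene is expressed in all samples; cannot compute size factors")
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - logg[use]))
  })
  if (any(!is.finite(sf) | sf <= 0)) stop("non-positive size factor")
  sf
}

#' Per-treatment differential expression against matched vehicle controls
#'
#' The internal method normalizes counts by median-of-ratios size factors
#' and, for each (gene, treatment-vs-control) comparison, reports
#' `log2fc = log2((mean_t + c0) / (mean_c + c0))` with pseudocount
#' `c0 = 0.5`, a Wald p-value from `log2fc / SE` under a negative-binomial
#' model with a method-of-moments dispersion (floored at 1e-8), and
#' Benjamini-Hochberg adjusted p-values within each comparison. The Wald
#' statistic is referred to a t distribution with `n_t + n_c - 2` degrees of
#' freedom as a small-sample correction (groups here have 2-8 replicates).
#'
#' `method = "external_table"` instead ingests a precomputed table with the
#' same schema (gene, treatment, log2fc, p, padj), e.g. published DESeq2
#' output, enabling exact replication of a study's DE stage.
#'
#' @param counts genes x samples count matrix.
#' @param sheet sample sheet (see [read_sample_sheet()]).
#' @param method "internal_nb_wald" or "external_table".
#' @param external_path path of the external DE TSV (external_table only).
#' @param c0 pseudocount on normalized means (default 0.5).
#' @return data.frame with columns gene, treatment, log2fc, p, padj.
#' @export
differential_expression <- function(counts, sheet,
                                    method = c("internal_nb_wald",
                                               "external_table"),
                                    external_path = NULL, c0 = 0.5) {
  method <- match.arg(method)
  if (method == "external_table") {
    if (is.null(external_path)) stop("external_table requires 'external_path'")
    return(read_de_table(external_path))
  }
  validate_sample_sheet(sheet)
  ctrl_of <- treatment_controls(sheet)
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")

  res <- vector("list", length(ctrl_of))
  for (i in seq_along(ctrl_of)) {
    t <- names(ctrl_of)[i]
    st <- sheet$sample[sheet$treatment == t]
    sc <- sheet$sample[sheet$treatment == ctrl_of[[t]]]
    if (length(st) < 2 || length(sc) < 2)
      stop("treatment ", t, " or its control has fewer than 2 replicates")
    xt <- norm[, st, drop = FALSE]
    xc <- norm[, sc, drop = FALSE]
    nt <- ncol(xt); nc <- ncol(xc)
    mt <- rowMeans(xt); mc <- rowMeans(xc)
    vt <- apply(xt, 1, var); vc <- apply(xc, 1, var)
    lfc <- log2((mt + c0) / (mc + c0))
    # moment dispersion pooled over the two groups, floored
    alpha <- pmax(((vt - mt) + (vc - mc)) / (mt^2 + mc^2 + 1e-12), 1e-8)
    se_ln2 <- (1 / mt.safe(mt, c0) + alpha) / nt +
      (1 / mt.safe(mc, c0) + alpha) / nc
    se_log2 <- sqrt(se_ln2) / log(2)
    z <- lfc / se_log2
    p <- 2 * pt(-abs(z), df = nt + nc - 2)
    res[[i]] <- data.frame(gene = rownames(counts), treatment = t,
                           log2fc = lfc, p = p,
                           padj = p.adjust(p, method = "BH"),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, res)
}

mt.safe <- function(m, c0) pmax(m, c0)

#' Keep genes responding in enough comparisons
#'
#' A gene survives when its adjusted p-value is below `alpha` in at least
#' `min_comparisons` treatments (no fold-change cutoff). This is the
#' network-input filter: genes never responding to any chemical carry no
#' co-expression signal.
#'
#' @param det DE table.
#' @param min_comparisons minimum number of significant comparisons
#'   (default 3).
#' @param alpha adjusted p-value threshold (default 0.05).
#' @param use_adjusted filter on `padj` (default) or raw `p`.
#' @return character vector of surviving gene ids, input order preserved.
#' @export
filter_de_genes <- function(det, min_comparisons = 3, alpha = 0.05,
                            use_adjusted = TRUE) {
  stopifnot(nrow(det) > 0)
  pv <- if (use_adjusted) det$padj else det$p
  hits <- tapply(pv < alpha, det$gene, sum)
  keep <- names(hits)[hits >= min_comparisons]
  unique(det$gene)[unique(det$gene) %in% keep]
}

#' Assemble the genes x treatments log2 fold-change matrix
#'
#' @param det DE table.
#' @param genes gene ids to keep (row order preserved from this vector).
#' @return numeric matrix, rows = `genes`, columns = treatments in the DE
#'   table's order of first appearance.
#' @export
build_fc_matrix <- function(det, genes) {
  treatments <- unique(det$treatment)
  miss <- setdiff(genes, det$gene)
  if (length(miss)) stop("genes absent from the DE table: ",
                         paste(head(miss, 5), collapse = ", "))
  fc <- matrix(NA_real_, length(genes), length(treatments),
               dimnames = list(genes, treatments))
  idx <- cbind(match(det$gene, genes), match(det$treatment, treatments))
  ok <- !is.na(idx[, 1])
  fc[idx[ok, , drop = FALSE]] <- det$log2fc[ok]
  if (anyNA(fc)) stop("missing (gene, treatment) cell(s) in the DE table")
  fc
}

#' Ward clustering of treatments by their fold-change profiles
#'
#' Agglomerative hierarchical clustering (Ward.D2 criterion) of treatment
#' columns on Euclidean distance, cut into `k` clusters.
#'
#' @param fc genes x treatments log2FC matrix.
#' @param k number of clusters (default 6).
#' @return list with `tree` (hclust) and `clusters` (named integer vector).
#' @export
ward_cluster_treatments <- function(fc, k = 6) {
  stopifnot(k >= 1, k <= ncol(fc))
  d <- dist(t(fc))
  tree <- hclust(d, method = "ward.D2")
  list(tree = tree, clusters = cutree(tree, k = k))
}

#' Response criteria for calling a gene responsive to a chemical
#'
#' Two conventions appear in this kind of analysis: an FDR-only call
#' (`alpha = 0.05`, `min_abs_lfc = 0`, adjusted p) and a stricter DEG call
#' (`p < 0.05` and `|log2FC| > 1`).
#'
#' @param alpha p-value threshold in (0, 1].
#' @param min_abs_lfc minimum |log2FC| (strict inequality), >= 0.
#' @param use_adjusted use `padj` (TRUE) or raw `p` (FALSE).
#' @return a `response_criteria` list.
#' @export
response_criteria <- function(alpha = 0.05, min_abs_lfc = 0,
                              use_adjusted = TRUE) {
  stopifnot(alpha > 0, alpha <= 1, min_abs_lfc >= 0)
  structure(list(alpha = alpha, min_abs_lfc = min_abs_lfc,
                 use_adjusted = use_adjusted), class = "response_criteria")
}

#' Count the chemicals of a class a gene responds to
#'
#' @param det DE table.
#' @param gene gene id.
#' @param treatments treatments to consider (e.g. the members of one
#'   chemical class); NULL = all treatments in `det`.
#' @param crit a [response_criteria()] object.
#' @return integer count.
#' @export
count_responsive_chemicals <- function(det, gene, treatments = NULL,
                                       crit = response_criteria()) {
  rows <- det[det$gene == gene, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown gene: ", gene)
  if (!is.null(treatments))
    rows <- rows[rows$treatment %in% treatments, , drop = FALSE]
  pv <- if (crit$use_adjusted) rows$padj else rows$p
  sum(pv < crit$alpha & abs(rows$log2fc) > crit$min_abs_lfc)
}
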
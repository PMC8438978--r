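#' Hypergeometric over-representation of a gene list
#'
#' One-sided hypergeometric upper-tail test (probability of an overlap at
#' least as large as observed) of a gene list against every set of a GMT
#' collection, with Benjamini-Hochberg adjustment across the sets tested. A
#' set is flagged `enriched` when its raw p-value is below `alpha` AND the
#' observed overlap exceeds its expectation (over-representation only;
#' under-represented sets are never flagged).
#'
#' @param genes character vector of gene ids (e.g. one module).
#' @param gsc gene-set collection from [read_gmt()].
#' @param alpha enrichment threshold on the raw p-value (default 0.05; the
#'   adjusted p-value is also reported).
#' @param module_id optional id copied into the output.
#' @return data.frame (module, set, overlap, module_size, set_size,
#'   universe_size, expected, p, padj, enriched) sorted by p.
#' @export
overrepresentation <- function(genes, gsc, alpha = 0.05, module_id = NA) {
  genes <- unique(genes)
  outside <- setdiff(genes, gsc$universe)
  if (length(outside) == length(genes)) stop("empty module after universe restriction")
  genes <- setdiff(genes, outside)
  U <- length(gsc$universe)
  k <- length(genes)
  rows <- lapply(names(gsc$sets), function(nm) {
    set <- gsc$sets[[nm]]
    m <- length(set)
    ov <- length(intersect(genes, set))
    p <- phyper(ov - 1, m, U - m, k, lower.tail = FALSE)
    data.frame(module = module_id, set = nm, overlap = ov, module_size = k,
               set_size = m, universe_size = U, expected = k * m / U,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "BH")
  out$enriched <- out$p < alpha & out$overlap > out$expected
  out[order(out$p, out$set), ]
}

#' Over-representation of every module in a partition
#'
#' Runs [overrepresentation()] for each assigned module and applies the BH
#' adjustment across all (module, set) tests jointly.
#'
#' @param partition [detect_modules()] output.
#' @param gsc gene-set collection from [read_gmt()].
#' @param alpha raw-p enrichment threshold (default 0.05).
#' @return combined data.frame, sorted by module then p.
#' @export
module_enrichment <- function(partition, gsc, alpha = 0.05) {
  mods <- sort(unique(partition$module[!is.na(partition$module)]))
  res <- lapply(mods, function(m) {
    overrepresentation(partition$gene[!is.na(partition$module) &
                                        partition$module == m],
                       gsc, alpha = alpha, module_id = m)
  })
  out <- do.call(rbind, res)
  out$padj <- p.adjust(out$p, method = "BH")
  out <- out[order(out$module, out$p, out$set), ]
  rownames(out) <- NULL
  out
}
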
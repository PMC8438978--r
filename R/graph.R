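#' Build the directed co-expression network
#'
#' @param edges edge list data.frame (regulator, target, weight) as produced
#'   by [threshold_edges()].
#' @return an igraph directed graph with a `weight` edge attribute.
#' @export
build_graph <- function(edges) {
  if (nrow(edges) == 0) stop("empty edge list")
  if (any(edges$regulator == edges$target)) stop("self-edges are not allowed")
  if (anyDuplicated(edges[, c("regulator", "target")]))
    stop("duplicate (regulator, target) pairs")
  igraph::graph_from_data_frame(edges, directed = TRUE)
}

#' Largest weakly connected component
#'
#' Ties between equally large components are broken in favour of the
#' component containing the lexicographically smallest node id.
#'
#' @param net igraph graph.
#' @return the induced subgraph on the main component.
#' @export
main_component <- function(net) {
  comp <- igraph::components(net, mode = "weak")
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(ci) {
      min(igraph::V(net)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(firsts)][1]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Detect size-ranked co-expression modules
#'
#' Greedy modularity maximization (Clauset-Newman-Moore, as in igraph's
#' fastgreedy community detection) on the undirected simplification of the
#' network, with reciprocal edge weights summed. Communities smaller than
#' `min_size` are left unassigned (`NA`). Module ids are assigned by
#' decreasing size starting at 1; equally sized modules are ordered by their
#' smallest member gene id.
#'
#' @param net igraph directed graph with `weight` edge attribute.
#' @param min_size smallest reported module (default 12).
#' @return data.frame (gene, module) with a `sizes` attribute (named integer
#'   vector of module sizes).
#' @export
detect_modules <- function(net, min_size = 12) {
  und <- igraph::as_undirected(net, mode = "collapse",
                               edge.attr.comb = list(weight = "sum"))
  cl <- igraph::cluster_fast_greedy(und)
  memb <- igraph::membership(cl)
  genes <- igraph::V(und)$name
  tab <- table(memb)
  keep <- names(tab)[tab >= min_size]
  first_gene <- vapply(keep, function(m) min(genes[memb == m]), character(1))
  keep <- keep[order(-tab[keep], first_gene)]
  remap <- setNames(seq_along(keep), keep)
  module <- unname(remap[as.character(memb)])
  out <- data.frame(gene = genes, module = as.integer(module),
                    stringsAsFactors = FALSE)
  sizes <- vapply(seq_along(keep), function(i) sum(module == i, na.rm = TRUE),
                  integer(1))
  attr(out, "sizes") <- setNames(sizes, seq_along(keep))
  out
}

#' Degree and betweenness centrality of every gene
#'
#' Indegree and outdegree count directed edges into and out of the gene;
#' degree is their sum. Betweenness is directed shortest-path betweenness on
#' the unweighted graph, normalized by `(n - 1) * (n - 2)` so values lie in
#' `[0, 1]`. High-degree genes are "hubs", high-betweenness genes
#' "bottlenecks".
#'
#' @param net igraph directed graph.
#' @param partition optional [detect_modules()] output; adds a module column.
#' @return data.frame (gene, betweenness, degree, indegree, outdegree, and
#'   module if a partition is supplied).
#' @export
centrality <- function(net, partition = NULL) {
  n <- igraph::vcount(net)
  if (n == 0) stop("empty network")
  genes <- igraph::V(net)$name
  indeg <- igraph::degree(net, mode = "in")
  outdeg <- igraph::degree(net, mode = "out")
  btw <- igraph::betweenness(net, directed = TRUE, weights = NA)
  norm <- if (n > 2) (n - 1) * (n - 2) else 1
  out <- data.frame(gene = genes,
                    betweenness = unname(btw) / norm,
                    degree = unname(indeg + outdeg),
                    indegree = unname(indeg),
                    outdegree = unname(outdeg),
                    stringsAsFactors = FALSE)
  if (!is.null(partition))
    out$module <- partition$module[match(out$gene, partition$gene)]
  rownames(out) <- NULL
  out
}

#' Top genes by a centrality measure
#'
#' @param tab [centrality()] output.
#' @param by "degree" or "betweenness".
#' @param n how many genes (default 20).
#' @return the top `n` rows, ties broken by gene id.
#' @export
top_central <- function(tab, by = c("degree", "betweenness"), n = 20) {
  by <- match.arg(by)
  stopifnot(n <= nrow(tab))
  tab[order(-tab[[by]], tab$gene), , drop = FALSE][seq_len(n), , drop = FALSE]
}

#' k-th order network neighborhood of a gene
#'
#' Neighbors are direction-blind: any gene sharing an edge with the seed (in
#' either direction) is in the first shell; genes adjacent to the first
#' shell and not already included form the second shell. Returns the induced
#' subgraph over seed + shells.
#'
#' @param net igraph directed graph.
#' @param gene seed gene id.
#' @param order 1 or 2.
#' @return list with `subgraph` (igraph), `nodes` (data.frame gene, shell),
#'   `n_nodes`, `n_edges`.
#' @export
neighborhood <- function(net, gene, order = 2) {
  stopifnot(order %in% c(1, 2))
  vnames <- igraph::V(net)$name
  if (!gene %in% vnames) stop("gene absent from network: ", gene)
  d <- igraph::distances(net, v = gene, mode = "all", weights = NA)[1, ]
  keep <- vnames[is.finite(d) & d <= order]
  sub <- igraph::induced_subgraph(net, keep)
  shell <- d[is.finite(d) & d <= order]
  nodes <- data.frame(gene = keep, shell = as.integer(shell),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$shell, nodes$gene), ]
  rownames(nodes) <- NULL
  list(seed = gene, order = order, subgraph = sub, nodes = nodes,
       n_nodes = igraph::vcount(sub), n_edges = igraph::ecount(sub))
}

#' Per-gene and per-module chemical-response counts
#'
#' For each gene in the partition, counts how many chemicals of the given
#' class it responds to (see [count_responsive_chemicals()]); summarizes the
#' counts per module (mean and max) to flag class-associated modules.
#'
#' @param partition [detect_modules()] output.
#' @param det DE table.
#' @param treatments treatments defining the chemical class (NULL = all).
#' @param crit a [response_criteria()] object.
#' @return list with `genes` (gene, module, n_responsive) and `modules`
#'   (module, size, mean_responsive, max_responsive), modules sorted by
#'   decreasing mean response.
#' @export
module_response_profile <- function(partition, det, treatments = NULL,
                                    crit = response_criteria()) {
  pv <- if (crit$use_adjusted) det$padj else det$p
  hit <- pv < crit$alpha & abs(det$log2fc) > crit$min_abs_lfc
  if (!is.null(treatments)) hit <- hit & det$treatment %in% treatments
  counts <- tapply(hit, det$gene, sum)
  genes <- data.frame(
    gene = partition$gene,
    module = partition$module,
    n_responsive = as.integer(counts[partition$gene]),
    stringsAsFactors = FALSE
  )
  genes$n_responsive[is.na(genes$n_responsive)] <- 0L
  assigned <- genes[!is.na(genes$module), , drop = FALSE]
  mods <- do.call(rbind, lapply(split(assigned, assigned$module), function(g) {
    data.frame(module = g$module[1], size = nrow(g),
               mean_responsive = mean(g$n_responsive),
               max_responsive = max(g$n_responsive))
  }))
  mods <- mods[order(-mods$mean_responsive, mods$module), , drop = FALSE]
  rownames(mods) <- NULL
  list(genes = genes, modules = mods)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' used to compare recovered modules with planted ground truth. Items with
#' `NA` in either labeling are dropped.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
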
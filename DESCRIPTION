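Package: coexpnet
Title: Chemical Gene Co-Expression Network Analysis for Multi-Treatment
    RNA-Seq Compendia
Version: 0.1.0
Authors@R:
    person("Network", "Toxicology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers directed gene co-expression networks from compendia of
    chemical-exposure RNA-seq experiments. Starting from a gene-by-sample
    count matrix with treatment/vehicle-control pairing, the pipeline
    filters low-expression and non-responsive genes, computes per-treatment
    log2 fold changes against matched controls, scores every ordered gene
    pair by random-forest regression importance of one gene's fold-change
    profile for another's, thresholds the importances into a directed
    network, detects size-ranked modules by greedy modularity, ranks hubs
    and bottlenecks by degree and betweenness centrality, extracts k-th
    order network neighborhoods, tests module gene lists for
    over-representation against GMT gene-set collections, and quantifies
    chemical-class-specific co-expression by comparing leave-class-out
    networks with a resampled random-removal null. A negative-binomial
    simulator with planted class-specific modules and designated hub genes
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
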
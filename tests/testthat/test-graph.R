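edge_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(regulator = m[, 1], target = m[, 2], weight = 1,
             stringsAsFactors = FALSE)
}

test_that("graph construction validates the edge list", {
  expect_error(build_graph(edge_df("a", "a")), "self-edges")
  expect_error(build_graph(rbind(edge_df("a", "b"), edge_df("a", "b"))),
               "duplicate")
  expect_error(build_graph(edge_df("a", "b")[0, ]), "empty")
})

test_that("main component extraction and its tie rule", {
  # two triangles, tie on size: the one with the smallest node id wins
  el <- edge_df("b1", "b2", "b2", "b3", "b3", "b1",
                "a1", "a2", "a2", "a3", "a3", "a1")
  main <- main_component(build_graph(el))
  expect_setequal(igraph::V(main)$name, c("a1", "a2", "a3"))
  # single edge -> component of 2
  expect_equal(igraph::vcount(main_component(build_graph(edge_df("x", "y")))), 2)
  # hand-drawn 7-node graph: 5-node component beats 2-node component
  el7 <- edge_df("p", "q", "q", "r", "r", "s", "s", "t", "t", "p", "u", "v")
  main7 <- main_component(build_graph(el7))
  expect_setequal(igraph::V(main7)$name, c("p", "q", "r", "s", "t"))
})

test_that("module detection recovers planted cliques and ranks by size", {
  # two cliques (sizes 20 and 14) joined by one edge
  clique_edges <- function(nodes) {
    pr <- t(combn(nodes, 2))
    data.frame(regulator = pr[, 1], target = pr[, 2], weight = 1,
               stringsAsFactors = FALSE)
  }
  n1 <- sprintf("a%02d", 1:20); n2 <- sprintf("b%02d", 1:14)
  el <- rbind(clique_edges(n1), clique_edges(n2), edge_df("a01", "b01"))
  part <- detect_modules(build_graph(el), min_size = 12)
  expect_equal(unname(attr(part, "sizes")), c(20L, 14L))
  expect_equal(unique(part$module[part$gene %in% n1]), 1L)   # biggest first
  expect_equal(unique(part$module[part$gene %in% n2]), 2L)
  # fully connected graph: no multi-module structure (igraph's greedy
  # agglomeration may leave a stray singleton at modularity 0, which falls
  # below min_size and is reported unassigned)
  el_full <- clique_edges(sprintf("c%02d", 1:15))
  part_full <- detect_modules(build_graph(el_full), min_size = 12)
  expect_equal(length(attr(part_full, "sizes")), 1L)
  expect_setequal(na.omit(unique(part_full$module)), 1L)
  # communities below min_size unassigned
  el_small <- rbind(clique_edges(n1), clique_edges(sprintf("d%d", 1:5)),
                    edge_df("a01", "d1"))
  part_small <- detect_modules(build_graph(el_small), min_size = 12)
  expect_true(all(is.na(part_small$module[part_small$gene %in%
                                            sprintf("d%d", 1:5)])))
})

test_that("module recovery on the synthetic compendium is faithful", {
  sim <- small_compendium()
  cm <- filter_low_expression(sim$counts)
  det <- differential_expression(cm, sim$samples)
  genes <- filter_de_genes(det)
  fc <- build_fc_matrix(det, genes)
  w <- infer_weight_matrix(fc, n_trees = 150, seed = 31)
  net <- main_component(build_graph(threshold_edges(w, min_weight = 0.00858)))
  part <- detect_modules(net)
  truth <- sim$truth$module_membership
  ari <- adjusted_rand_index(part$module[match(names(truth), part$gene)], truth)
  expect_gte(ari, 0.8)
})

test_that("centrality matches hand counts and the path-counting oracle", {
  # a->b, b->a, b->c: degree(b) = 3 = indegree 1 + outdegree 2
  el <- edge_df("a", "b", "b", "a", "b", "c")
  tab <- centrality(build_graph(el))
  b <- tab[tab$gene == "b", ]
  expect_equal(b$degree, 3); expect_equal(b$indegree, 1)
  expect_equal(b$outdegree, 2)
  expect_equal(tab$degree, tab$indegree + tab$outdegree)
  # directed 5-cycle: all equal, value from the enumeration oracle
  cyc <- edge_df("v1", "v2", "v2", "v3", "v3", "v4", "v4", "v5", "v5", "v1")
  tc <- centrality(build_graph(cyc))
  oc <- oracle_betweenness(cyc, sort(unique(c(cyc$regulator, cyc$target))))
  expect_equal(length(unique(round(tc$betweenness, 12))), 1)
  expect_equal(setNames(tc$betweenness, tc$gene)[names(oc)], oc,
               tolerance = 1e-9)
  # randomized oracle equivalence on graphs up to 30 nodes
  for (trial in 1:20) {
    g <- random_digraph(n = sample(5:30, 1), p_edge = 0.1, seed = 400 + trial)
    if (nrow(g$edges) == 0) next
    tab <- centrality(build_graph(g$edges))
    ora <- oracle_betweenness(g$edges, igraph::V(build_graph(g$edges))$name)
    expect_equal(setNames(tab$betweenness, tab$gene), ora, tolerance = 1e-9)
    expect_true(all(tab$betweenness >= 0 & tab$betweenness <= 1))
  }
})

test_that("top_central ranks with deterministic ties", {
  tab <- data.frame(gene = c("d", "b", "a", "c"),
                    betweenness = c(0.1, 0.3, 0.3, 0.2),
                    degree = c(5L, 2L, 2L, 9L),
                    indegree = 0L, outdegree = 0L, stringsAsFactors = FALSE)
  expect_equal(top_central(tab, "betweenness", 2)$gene, c("a", "b"))
  expect_equal(top_central(tab, "degree", 4)$gene, c("c", "d", "a", "b"))
  # star graph: hub is top-1 by degree
  star <- edge_df("hub", "l1", "hub", "l2", "hub", "l3", "hub", "l4")
  tc <- centrality(build_graph(star))
  expect_equal(top_central(tc, "degree", 1)$gene, "hub")
  expect_error(top_central(tab, "degree", 10))
})

test_that("neighborhoods are direction-blind shells", {
  star <- edge_df("hub", "l1", "l2", "hub", "hub", "l3")
  nb <- neighborhood(build_graph(star), "hub", order = 1)
  expect_equal(nb$n_nodes, 4)   # whole star despite mixed directions
  expect_equal(nb$nodes$shell[nb$nodes$gene == "hub"], 0L)
  # path a-b-c-d-e from seed c, order 2: shells {b,d} then {a,e}
  path <- edge_df("a", "b", "b", "c", "c", "d", "d", "e")
  nb2 <- neighborhood(build_graph(path), "c", order = 2)
  expect_equal(nb2$n_nodes, 5)
  expect_setequal(nb2$nodes$gene[nb2$nodes$shell == 1], c("b", "d"))
  expect_setequal(nb2$nodes$gene[nb2$nodes$shell == 2], c("a", "e"))
  nb1 <- neighborhood(build_graph(path), "c", order = 1)
  expect_setequal(nb1$nodes$gene, c("b", "c", "d"))
  expect_equal(nb1$n_edges, 2)
  # isolated gene -> subnetwork of size 1
  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices("lone")
  nbi <- neighborhood(g, "lone", order = 2)
  expect_equal(nbi$n_nodes, 1)
  expect_error(neighborhood(build_graph(path), "zz"), "absent")
})

test_that("module response profiles agree with per-gene counting", {
  part <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                     module = c(1L, 1L, 2L, NA), stringsAsFactors = FALSE)
  det <- toy_de(paste0("g", 1:4), paste0("T", 1:3),
                log2fc = rep(c(2, 2, 0, 2), 3),
                padj = rep(c(0.01, 0.01, 0.5, 0.01), 3))
  pr <- module_response_profile(part, det)
  for (g in part$gene)
    expect_equal(pr$genes$n_responsive[pr$genes$gene == g],
                 count_responsive_chemicals(det, g))
  # module 1 fully responsive, ranks first
  expect_equal(pr$modules$module[1], 1L)
  expect_equal(pr$modules$mean_responsive[1], 3)
  expect_equal(pr$modules$mean_responsive[pr$modules$module == 2], 0)
  # impossible criterion -> all zeros
  pr0 <- module_response_profile(part, det,
                                 crit = response_criteria(alpha = 1e-9))
  expect_true(all(pr0$genes$n_responsive == 0))
})

test_that("adjusted Rand index behaves", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  set.seed(1)
  a <- sample(1:3, 300, replace = TRUE)
  b <- sample(1:3, 300, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.1)
  # NA labels are ignored
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, NA), c(3, 3, 4, 4, 9)), 1)
})
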
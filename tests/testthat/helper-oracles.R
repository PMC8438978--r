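`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used by the dual-route checks. Everything here is
# deliberately naive and shares no code with the package.

# Directed betweenness by the combinatorial identity
#   sigma_st(v) = sigma(s, v) * sigma(v, t)  when d(s,v) + d(v,t) = d(s,t):
# BFS from every source gives distances and shortest-path counts; no
# dependency accumulation (Brandes) is used.
oracle_betweenness <- function(edges, nodes) {
  n <- length(nodes)
  adj <- lapply(setNames(seq_len(n), nodes), function(i) integer(0))
  for (r in seq_len(nrow(edges))) {
    a <- match(edges$regulator[r], nodes)
    b <- match(edges$target[r], nodes)
    adj[[a]] <- c(adj[[a]], b)
  }
  d <- matrix(Inf, n, n)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0; sig[s, s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (is.infinite(d[s, v])) {
            d[s, v] <- d[s, u] + 1
            nxt <- c(nxt, v)
          }
          if (d[s, v] == d[s, u] + 1) sig[s, v] <- sig[s, v] + sig[s, u]
        }
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      if (s == v) next
      for (t in seq_len(n)) {
        if (t == v || t == s || sig[s, t] == 0) next
        if (d[s, v] + d[v, t] == d[s, t])
          btw[v] <- btw[v] + sig[s, v] * sig[v, t] / sig[s, t]
      }
    }
  }
  if (n > 2) btw <- btw / ((n - 1) * (n - 2))
  setNames(btw, nodes)
}

# Exhaustive best-stump oracle: maximum variance reduction over all
# predictors and all split midpoints, impurity = sum of squared deviations,
# normalized by the number of observations.
oracle_best_stump <- function(X, y) {
  n <- length(y)
  imp <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  best <- 0
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    for (cut in (head(xs, -1) + xs[-1]) / 2) {
      l <- y[X[, j] <= cut]; r <- y[X[, j] > cut]
      red <- imp(y) - imp(l) - imp(r)
      if (red > best) best <- red
    }
  }
  best / n
}

# Exact hypergeometric upper tail by direct summation of the pmf.
oracle_hyper_tail <- function(overlap, set_size, universe, module_size) {
  i <- seq(overlap, min(set_size, module_size))
  sum(choose(set_size, i) * choose(universe - set_size, module_size - i)) /
    choose(universe, module_size)
}

# Brute-force Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  padj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) padj[i] <- min(padj[i], padj[i + 1])
  padj <- pmin(padj, 1)
  out <- numeric(n)
  out[o] <- padj
  out
}

# Random simple directed graph as an edge-list data.frame.
random_digraph <- function(n, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(regulator = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  keep <- runif(nrow(pairs)) < p_edge
  el <- pairs[keep, , drop = FALSE]
  el$weight <- rep(1, nrow(el))
  rownames(el) <- NULL
  list(edges = el, nodes = nodes)
}
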
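## Independent brute-force oracles and fixture builders. Everything here is
## deliberately written as plain loops over definitions, independent of the
## package's implementation paths.

## --- set partitions ---------------------------------------------------------

## All partitions of n items as restricted-growth label vectors.
oracle_all_partitions <- function(n) {
  out <- list()
  rec <- function(pref, mx) {
    if (length(pref) == n) {
      out[[length(out) + 1L]] <<- pref
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(pref, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

## Modularity by the definition, looping over communities.
oracle_modularity <- function(adj, memb) {
  m <- sum(adj) / 2
  d <- rowSums(adj)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    q <- q + sum(adj[idx, idx]) / (2 * m) - (sum(d[idx]) / (2 * m))^2
  }
  q
}

## Exhaustive maximum-modularity partition.
oracle_best_partition <- function(adj) {
  ps <- oracle_all_partitions(nrow(adj))
  qs <- vapply(ps, function(p) oracle_modularity(adj, p), 0)
  list(q = max(qs), memb = ps[[which.max(qs)]])
}

## --- IPW building blocks (explicit loops) -----------------------------------

oracle_policy_prob <- function(a, alpha) {
  p <- 1
  for (aj in a) p <- p * if (aj == 1) alpha else (1 - alpha)
  p
}

oracle_group_ipw_mean <- function(A, Y, f, alpha, arm) {
  n <- length(A)
  tot <- 0
  for (j in seq_len(n)) {
    pij <- if (n == 1) 1 else oracle_policy_prob(A[-j], alpha)
    tot <- tot + pij * (A[j] == arm) * Y[j]
  }
  tot / (n * f)
}

oracle_group_ipw_marginal <- function(A, Y, f, alpha) {
  sum(oracle_policy_prob(A, alpha) * Y) / (length(A) * f)
}

## Community propensity by direct numerical integration over the random
## intercept (trapezoid on a wide grid), independent of Gauss-Hermite.
oracle_community_f <- function(a, eta, sigma) {
  if (sigma == 0) {
    h <- 1 / (1 + exp(-eta))
    return(prod(ifelse(a == 1, h, 1 - h)))
  }
  bs <- seq(-10 * sigma, 10 * sigma, length.out = 20001L)
  vals <- vapply(bs, function(b) {
    h <- 1 / (1 + exp(-(eta + b)))
    prod(ifelse(a == 1, h, 1 - h)) * dnorm(b, 0, sigma)
  }, 0)
  sum((vals[-1L] + vals[-length(vals)]) / 2 * diff(bs))
}

## Normalized VOI straight from entropy definitions.
oracle_voi <- function(a1, a2) {
  n <- length(a1)
  tab <- table(a1, a2) / n
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (2 * ent(as.vector(tab)) - ent(rowSums(tab)) - ent(colSums(tab))) / log(n)
}

## --- fixture builders -------------------------------------------------------

## Named igraph from an edge string matrix.
graph_from_pairs <- function(...) {
  e <- c(...)
  igraph::make_graph(e, directed = FALSE)
}

two_triangles <- function() {
  graph_from_pairs("a", "b", "a", "c", "b", "c", "d", "e", "d", "f", "e", "f")
}

bridged_triangles <- function() {
  igraph::add_edges(two_triangles(), c("c", "d"))
}

## Planted two-block graph for the fixed detection suite: blocks of 3-5
## nodes, within-block edge probability 0.8 or 1, 1-2 bridge edges,
## connected. Draws from the current RNG state.
suite_graph <- function() {
  a <- sample(3:5, 1)
  b <- sample(3:5, 1)
  pw <- sample(c(0.8, 1), 1)
  nb <- sample(1:2, 1)
  repeat {
    n <- a + b
    adj <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
      same <- (i <= a) == (j <= a)
      if (same && runif(1) < pw) adj[i, j] <- adj[j, i] <- 1
    }
    for (k in seq_len(nb)) {
      i <- sample(seq_len(a), 1)
      j <- a + sample(seq_len(b), 1)
      adj[i, j] <- adj[j, i] <- 1
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- paste0("v", seq_len(n))
      return(list(graph = g, adj = adj, planted = rep(1:2, c(a, b))))
    }
  }
}

## Planted 4-block graph: dense blocks, sparse between.
planted_four_block <- function(block_size = 6L, p_within = 0.9,
                               n_between = 1L) {
  k <- 4L
  n <- k * block_size
  block <- rep(seq_len(k), each = block_size)
  repeat {
    adj <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
      if (block[i] == block[j] && runif(1) < p_within)
        adj[i, j] <- adj[j, i] <- 1
    }
    for (b1 in seq_len(k - 1L)) for (b2 in (b1 + 1L):k) {
      for (r in seq_len(n_between)) {
        i <- sample(which(block == b1), 1)
        j <- sample(which(block == b2), 1)
        adj[i, j] <- adj[j, i] <- 1
      }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (min(igraph::degree(g)) >= 1) {
      igraph::V(g)$name <- paste0("v", seq_len(n))
      return(list(graph = g, planted = block))
    }
  }
}

## Tiny attribute table + edges -> risk_network, for loader tests.
toy_network <- function() {
  edges <- data.frame(from = c("a", "b", "b", "c"),
                      to = c("b", "a", "c", "d"))
  attrs <- data.frame(id = c("a", "b", "c", "d", "e"),
                      treatment = c(1, 0, 1, 0, 0),
                      outcome = c(1, 0, NA, 1, 0),
                      x = c(0.1, -0.2, 0.5, 1, 2))
  risk_network(edges, attrs)
}

## Small synthetic validation configuration: strongly separated planted
## blocks, no missing outcomes, moderate community count.
validation_config <- function(n_communities = 30L, size_max = 8L) {
  synthetic_config(n_communities = n_communities, size_min = 3L,
                   size_max = size_max, size_meanlog = 1.6, size_sdlog = 0.4,
                   p_within = 0.6, p_between = 0.01,
                   miss_rate_intercept = -Inf)
}

## Evaluate expr with a local seed, restoring RNG state afterwards.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
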
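test_that("modularity matches hand-computed and oracle values", {
  g <- two_triangles()
  part <- setNames(rep(1:2, each = 3), letters[1:6])
  expect_equal(modularity_score(g, part), 0.5, tolerance = 1e-12)
  ## one community -> 0
  expect_equal(modularity_score(g, setNames(rep(1, 6), letters[1:6])), 0,
               tolerance = 1e-12)
  gb <- bridged_triangles()
  expect_equal(modularity_score(gb, part), 5 / 14, tolerance = 1e-12)
  expect_error(modularity_score(igraph::make_empty_graph(3, directed = FALSE),
                                rep(1, 3)), "empty edge")
  ## random partitions agree with the definitional loop
  set.seed(5)
  gr <- igraph::sample_gnp(15, 0.3)
  igraph::V(gr)$name <- paste0("v", 1:15)
  adj <- igraph::as_adjacency_matrix(gr, sparse = FALSE)
  for (i in 1:20) {
    memb <- sample(1:4, 15, replace = TRUE)
    expect_equal(modularity_score(gr, setNames(memb, paste0("v", 1:15))),
                 oracle_modularity(adj, memb), tolerance = 1e-12)
  }
  ## cross-check against igraph's implementation
  memb <- sample(1:3, 15, replace = TRUE)
  expect_equal(modularity_score(gr, setNames(memb, paste0("v", 1:15))),
               igraph::modularity(gr, memb), tolerance = 1e-12)
})

test_that("detectors recover canonical small structures", {
  for (m in c("cfg", "le")) {
    s <- detect_communities(two_triangles(), m)
    expect_equal(s$N, 2L)
    expect_equal(s$modularity, 0.5, tolerance = 1e-12)
    s <- detect_communities(bridged_triangles(), m)
    expect_equal(s$modularity, 5 / 14, tolerance = 1e-12)
  }
  ## single edge: one community
  se <- graph_from_pairs("a", "b")
  expect_equal(detect_communities(se, "cfg")$N, 1L)
  ## clique: no split improves Q
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(detect_communities(k5, "le")$N, 1L)
  ## barbell: two K4 blocks
  bb <- igraph::disjoint_union(igraph::make_full_graph(4),
                               igraph::make_full_graph(4))
  bb <- igraph::add_edges(bb, c(1, 5))
  igraph::V(bb)$name <- letters[1:8]
  for (m in c("cfg", "le")) {
    s <- detect_communities(bb, m)
    expect_equal(s$N, 2L)
    expect_true(all(s$assignment[1:4] == s$assignment[1]))
    expect_true(all(s$assignment[5:8] == s$assignment[5]))
  }
})

test_that("detected partitions are valid and self-consistent", {
  set.seed(11)
  for (i in 1:10) {
    gr <- igraph::sample_gnp(30, 0.12)
    gr <- igraph::induced_subgraph(gr, which(igraph::degree(gr) > 0))
    if (igraph::ecount(gr) < 2) next
    igraph::V(gr)$name <- paste0("v", seq_len(igraph::vcount(gr)))
    for (m in c("cfg", "le")) {
      s <- detect_communities(gr, m)
      ## total assignment with contiguous labels
      expect_setequal(names(s$assignment), igraph::V(gr)$name)
      expect_equal(sort(unique(s$assignment)), seq_len(s$N))
      expect_equal(sum(s$sizes), igraph::vcount(gr))
      ## stored Q equals recomputed Q
      expect_equal(s$modularity, modularity_score(gr, s$assignment),
                   tolerance = 1e-12)
      expect_true(s$modularity >= -1 && s$modularity <= 1)
    }
  }
})

test_that("detection on a disconnected graph equals per-component detection", {
  set.seed(21)
  g1 <- planted_four_block(4L)$graph
  g2 <- two_triangles()
  igraph::V(g2)$name <- paste0("t", 1:6)
  g <- igraph::disjoint_union(g1, g2)
  igraph::V(g)$name <- c(igraph::V(g1)$name, igraph::V(g2)$name)
  for (m in c("cfg", "le")) {
    s_all <- detect_communities(g, m)
    s1 <- detect_communities(g1, m)
    s2 <- detect_communities(g2, m)
    ## restriction to each component matches the standalone run (up to labels)
    r1 <- s_all$assignment[igraph::V(g1)$name]
    r2 <- s_all$assignment[igraph::V(g2)$name]
    expect_true(netspill:::same_partition(r1, s1$assignment[names(r1)]))
    expect_true(netspill:::same_partition(r2, s2$assignment[names(r2)]))
  }
})

test_that("strongly separated planted blocks are recovered in nearly all replicates", {
  ## two planted blocks of 10-12 nodes, within-block edge probability 0.8
  ## versus 0.02 between (40x separation)
  set.seed(31)
  hits <- c(cfg = 0L, le = 0L)
  reps <- 40L
  for (i in seq_len(reps)) {
    block <- rep(1:2, c(12L, 10L))
    n <- length(block)
    repeat {
      adj <- matrix(0, n, n)
      for (a in seq_len(n)) for (b in seq_len(a - 1L)) {
        p <- if (block[a] == block[b]) 0.8 else 0.02
        if (runif(1) < p) adj[a, b] <- adj[b, a] <- 1
      }
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      if (igraph::is_connected(g)) break
    }
    igraph::V(g)$name <- paste0("v", seq_len(n))
    planted <- setNames(block, igraph::V(g)$name)
    for (m in c("cfg", "le")) {
      s <- detect_communities(g, m)
      if (netspill:::same_partition(s$assignment[names(planted)], planted))
        hits[m] <- hits[m] + 1L
    }
  }
  expect_gte(hits[["cfg"]], ceiling(0.95 * reps))
  expect_gte(hits[["le"]], ceiling(0.95 * reps))
  ## greedy agglomeration also recovers a 4-block layout reliably
  set.seed(32)
  hits4 <- 0L
  for (i in seq_len(20L)) {
    pb <- planted_four_block(6L, p_within = 0.9, n_between = 1L)
    planted <- setNames(pb$planted, igraph::V(pb$graph)$name)
    s <- detect_communities(pb$graph, "cfg")
    if (netspill:::same_partition(s$assignment[names(planted)], planted))
      hits4 <- hits4 + 1L
  }
  expect_gte(hits4, 19L)
})

test_that("detectors are deterministic and match igraph on structured graphs", {
  pb <- with_seed_local(77, planted_four_block(5L))
  s1 <- detect_communities(pb$graph, "cfg")
  s2 <- detect_communities(pb$graph, "cfg")
  expect_identical(s1$assignment, s2$assignment)
  ## igraph agreement on a clearly structured graph (soft cross-check)
  qi <- igraph::modularity(pb$graph,
    igraph::membership(igraph::cluster_fast_greedy(pb$graph)))
  expect_equal(s1$modularity, qi, tolerance = 1e-9)
  sle <- detect_communities(pb$graph, "le")
  qle <- igraph::modularity(pb$graph,
    igraph::membership(igraph::cluster_leading_eigen(pb$graph)))
  expect_equal(sle$modularity, qle, tolerance = 1e-9)
})

test_that("leading eigenvector works beyond the dense eigen-decomposition limit", {
  ## components above 256 nodes take the iterative solver path; the constant
  ## vector is a null eigenvector of the generalized modularity matrix and
  ## must not trap the iteration
  set.seed(91)
  g <- igraph::sample_gnp(300, 0.02)
  g <- igraph::induced_subgraph(g, which(igraph::degree(g) > 0))
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  s <- detect_communities(g, "le")
  expect_gt(s$N, 1L)
  q_ig <- igraph::modularity(g, igraph::membership(igraph::cluster_leading_eigen(g)))
  expect_equal(s$modularity, q_ig, tolerance = 1e-9)
})
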
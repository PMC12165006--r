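test_that("VOI matches analytic cases and the entropy oracle", {
  ids <- paste0("v", 1:4)
  same <- setNames(c(1, 1, 2, 2), ids)
  expect_equal(voi(same, same), 0)
  ## singletons vs one block on n = 4: exactly 1
  expect_equal(voi(setNames(1:4, ids), setNames(rep(1, 4), ids)), 1,
               tolerance = 1e-12)
  ## {12|34} vs {13|24}: also 1 (2 log 2 / log 4)
  expect_equal(voi(setNames(c(1, 1, 2, 2), ids), setNames(c(1, 2, 1, 2), ids)),
               1, tolerance = 1e-12)
  expect_error(voi(same, setNames(c(1, 1, 2, 2), paste0("w", 1:4))),
               "node sets")
  ## random partitions against the oracle
  set.seed(41)
  ids30 <- paste0("v", 1:30)
  for (i in 1:25) {
    a1 <- setNames(sample(1:5, 30, replace = TRUE), ids30)
    a2 <- setNames(sample(1:5, 30, replace = TRUE), ids30)
    expect_equal(voi(a1, a2), oracle_voi(a1[ids30], a2[ids30]),
                 tolerance = 1e-12)
  }
})

test_that("VOI is a metric: symmetry, identity, triangle inequality", {
  set.seed(42)
  ids <- paste0("v", 1:30)
  for (i in 1:100) {
    a <- setNames(sample(1:6, 30, replace = TRUE), ids)
    b <- setNames(sample(1:6, 30, replace = TRUE), ids)
    c_ <- setNames(sample(1:6, 30, replace = TRUE), ids)
    vab <- voi(a, b); vbc <- voi(b, c_); vac <- voi(a, c_)
    expect_equal(vab, voi(b, a), tolerance = 1e-12)
    expect_true(vab >= 0 && vab <= 1)
    expect_lte(vac, vab + vbc + 1e-12)
  }
})

test_that("perturbation preserves node and edge counts and moves the right number of edges", {
  study <- generate_study(synthetic_config(n_communities = 12), seed = 51)
  net <- study$network
  m <- igraph::ecount(net$graph)
  ## gamma = 0: identity
  p0 <- perturb_network(net, 0, seed = 1)
  expect_identical(netspill:::network_edges(p0), netspill:::network_edges(net))
  for (gamma in c(0.05, 0.3, 1)) {
    p <- perturb_network(net, gamma, seed = 2)
    expect_equal(igraph::ecount(p$graph), m)
    expect_setequal(network_ids(p), network_ids(net))
    ## exactly ceiling(gamma * m) original edges removed
    e_old <- paste(netspill:::network_edges(net)[, 1],
                   netspill:::network_edges(net)[, 2])
    e_new <- paste(netspill:::network_edges(p)[, 1],
                   netspill:::network_edges(p)[, 2])
    expect_equal(sum(!(e_old %in% e_new)), ceiling(gamma * m))
    ## simple graph preserved
    expect_false(igraph::any_multiple(p$graph))
    expect_false(any(igraph::which_loop(p$graph)))
  }
  ## degree-biased replacement variant also preserves counts
  pd <- perturb_network(net, 0.1, mode = "degree", seed = 3)
  expect_equal(igraph::ecount(pd$graph), m)
})

test_that("null network preserves the exact degree multiset and destroys structure", {
  study <- generate_study(synthetic_config(n_communities = 12), seed = 52)
  net <- study$network
  nn <- null_network(net, seed = 4)
  expect_equal(sort(igraph::degree(nn$graph)), sort(igraph::degree(net$graph)))
  expect_setequal(network_ids(nn), network_ids(net))
  ## modularity of detected structure drops on the null network in
  ## nearly all seeds
  set.seed(53)
  drops <- 0L
  reps <- 20L
  pb <- planted_four_block(6L)
  q_obs <- detect_communities(pb$graph, "cfg")$modularity
  for (i in seq_len(reps)) {
    nn2 <- null_network(pb$graph, seed = 100 + i)
    if (detect_communities(nn2, "cfg")$modularity < q_obs) drops <- drops + 1L
  }
  expect_gte(drops, ceiling(0.95 * reps))
})

test_that("perturbation curves degrade with gamma and null curves dominate", {
  set.seed(54)
  pb <- planted_four_block(6L, p_within = 0.9)
  ## gamma = 0 only: identically zero for a deterministic detector
  c0 <- perturbation_curve(pb$graph, "cfg", gammas = 0, reps = 5L, seed = 6)
  expect_true(all(c0$samples == 0))
  gam <- c(0.02, 0.06, 0.1, 0.5)
  obs <- perturbation_curve(pb$graph, "cfg", gammas = gam, reps = 10L,
                            seed = 7)
  expect_true(all(obs$summary$min <= obs$summary$mean + 1e-12))
  expect_true(all(obs$summary$mean <= obs$summary$max + 1e-12))
  expect_true(all(obs$samples >= 0 & obs$samples <= 1))
  ## stronger perturbation degrades the structure more on average
  expect_lt(obs$summary$mean[obs$summary$gamma == 0.02],
            obs$summary$mean[obs$summary$gamma == 0.5])
  ## null curve majorizes the observed curve at small gamma
  nn <- null_network(pb$graph, seed = 8)
  nul <- perturbation_curve(nn, "cfg", gammas = gam[1:3], reps = 10L,
                            seed = 9, network_tag = "null")
  expect_true(all(nul$summary$mean > obs$summary$mean[1:3]))
})

test_that("node-reassignment references are ordered and crossing points monotone", {
  set.seed(55)
  block <- rep(1:2, each = 50)
  str <- community_structure(setNames(block, paste0("v", 1:100)))
  r10 <- reassignment_reference(str, 0.10, reps = 200L, seed = 10)
  r20 <- reassignment_reference(str, 0.20, reps = 200L, seed = 10)
  expect_gt(r10, 0)
  expect_gt(r20, r10)
  ## reproducible under the same seed, close under another
  expect_equal(reassignment_reference(str, 0.10, reps = 200L, seed = 10), r10)
  r10b <- reassignment_reference(str, 0.10, reps = 200L, seed = 11)
  expect_equal(r10b, r10, tolerance = 0.05)
  ## single community cannot be reassigned
  expect_error(reassignment_reference(
    community_structure(setNames(rep(1, 10), paste0("v", 1:10))), 0.1),
    "at least 2")
  ## crossing points increase with the reference level
  curve <- list(summary = data.frame(gamma = c(0, 0.1, 0.2, 0.3),
                                     mean = c(0, 0.2, 0.5, 0.8)))
  class(curve) <- "perturbation_curve"
  g1 <- crossing_gamma(curve, 0.1)
  g2 <- crossing_gamma(curve, 0.4)
  expect_lt(g1, g2)
  expect_equal(g1, 0.05, tolerance = 1e-12)  # linear interpolation
  expect_true(is.na(crossing_gamma(curve, 0.9)))
})
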
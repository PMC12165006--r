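test_that("policy probabilities match hand values and normalize", {
  expect_equal(policy_prob(c(1, 0, 0), 0.2), 0.128, tolerance = 1e-12)
  expect_equal(policy_prob(c(1, 1), 1 - 1e-12), 1, tolerance = 1e-9)
  expect_equal(policy_prob_excluding(c(1, 0, 1), 2, 0.5), 0.25,
               tolerance = 1e-12)
  expect_equal(policy_prob_excluding(1, 1, 0.7), 1)
  expect_equal(policy_prob_excluding(c(1, 0), 1, 0.2), 0.8, tolerance = 1e-12)
  ## normalization over all 2^3 vectors
  tot <- 0
  for (k in 0:7) tot <- tot + policy_prob(as.integer(intToBits(k))[1:3], 0.3)
  expect_equal(tot, 1, tolerance = 1e-12)
  expect_error(policy_prob(c(1, 0), 1.2), "alpha")
})

test_that("group IPW estimators match hand values and the brute-force loop", {
  expect_equal(group_ipw_mean(c(1, 0), c(1, 1), 0.25, 0.5, 1), 1,
               tolerance = 1e-12)
  expect_equal(group_ipw_mean(c(1, 0), c(1, 1), 0.25, 0.5, 0), 1,
               tolerance = 1e-12)
  expect_equal(group_ipw_mean(c(1, 0), c(0, 0), 0.25, 0.5, 1), 0)
  expect_equal(group_ipw_marginal(c(1, 0), c(1, 1), 0.25, 0.5), 1,
               tolerance = 1e-12)
  expect_equal(group_ipw_marginal(c(1), c(1), 0.6, 0.6), 1, tolerance = 1e-12)
  expect_error(group_ipw_mean(c(1, 0), c(1, NA), 0.25, 0.5, 1), "missing")
  set.seed(12)
  for (i in 1:50) {
    n <- sample(1:8, 1)
    A <- rbinom(n, 1, 0.5); Y <- rbinom(n, 1, 0.6)
    f <- runif(1, 0.05, 1); al <- runif(1, 0.05, 0.95)
    for (arm in 0:1)
      expect_equal(group_ipw_mean(A, Y, f, al, arm),
                   oracle_group_ipw_mean(A, Y, f, al, arm),
                   tolerance = 1e-12)
    expect_equal(group_ipw_marginal(A, Y, f, al),
                 oracle_group_ipw_marginal(A, Y, f, al), tolerance = 1e-12)
  }
})

test_that("spillover_ipw validates inputs and excludes singletons", {
  study <- generate_study(validation_config(12L), seed = 21)
  net <- study$network
  ## singleton community triggers exclusion message
  memb <- study$truth$structure$assignment
  memb[1] <- max(memb) + 1L
  expect_message(
    spillover_ipw(net, community_structure(memb), ~ x_bin + x_age,
                  alphas = 0.5, pairs = cbind(0.6, 0.2)),
    "singleton")
  ## alpha <= alpha_prime rejected
  expect_error(spillover_ipw(net, study$truth$structure, ~ x_bin,
                             pairs = cbind(0.2, 0.6)), "alpha > alpha_prime")
  ## missing outcomes rejected
  study2 <- generate_study(synthetic_config(n_communities = 8), seed = 3)
  expect_error(spillover_ipw(study2$network, study2$truth$structure, ~ x_bin),
               "missing outcomes")
})

test_that("estimates satisfy the effect algebra and accounting identities", {
  study <- generate_study(validation_config(20L), seed = 22)
  fit <- suppressMessages(
    spillover_ipw(study$network, study$truth$structure, ~ x_bin + x_age))
  est <- fit$estimates
  ## TE(a, a') = DE(a) + SE(a, a') exactly
  for (r in which(est$effect == "total")) {
    de <- est$estimate[est$effect == "direct" & est$alpha == est$alpha[r]]
    se <- est$estimate[est$effect == "spillover" &
                         est$alpha == est$alpha[r] &
                         est$alpha_prime == est$alpha_prime[r]]
    expect_equal(est$estimate[r], de + se, tolerance = 1e-12)
  }
  ## overall = alpha-mix of arm means
  mu <- fit$mu
  for (al in fit$alphas) {
    expect_equal(mu[[paste0("mum_", al)]],
                 al * mu[[paste0("mu1_", al)]] +
                   (1 - al) * mu[[paste0("mu0_", al)]],
                 tolerance = 1e-12)
  }
  ## CI structure
  expect_equal(est$lower, est$estimate - 1.96 * est$se, tolerance = 1e-12)
  expect_equal(est$upper, est$estimate + 1.96 * est$se, tolerance = 1e-12)
  ## estimates finite, weights positive and finite
  expect_true(all(is.finite(est$estimate)) && all(is.finite(est$se)))
  w <- community_weights(fit)
  expect_true(all(w$weight >= 0 & is.finite(w$weight)))
  ## methods
  expect_named(coef(fit))
  expect_equal(nrow(confint(fit)), nrow(est))
  expect_output(print(fit), "Risk differences")
})

test_that("sandwich reduces to the CLT form when the propensity is known", {
  study <- generate_study(validation_config(25L), seed = 23)
  net <- study$network
  memb <- study$truth$structure$assignment[net$records$.id]
  cfgs <- study$config
  eta <- cfgs$treat_intercept + 0.5 * net$records$x_bin +
    0.3 * net$records$x_age
  logf <- netspill:::agh_log_f(net$records$.treatment, eta,
                               as.integer(factor(memb)), cfgs$sigma_b, 41L)
  f <- setNames(exp(logf), levels(factor(memb)))
  fit <- suppressMessages(
    spillover_ipw(net, study$truth$structure, known_f = f,
                  alphas = 0.5, pairs = cbind(0.6, 0.2)))
  ## SE of each mu equals population SD of per-community values / sqrt(N)
  tg <- fit$group_estimates
  N <- fit$N
  for (k in seq_len(ncol(tg))) {
    sd_pop <- sqrt(mean((tg[, k] - mean(tg[, k]))^2))
    expect_equal(sqrt(fit$vcov_mu[k, k]), sd_pop / sqrt(N), tolerance = 1e-8)
  }
})

test_that("sandwich SEs with estimated propensity agree with a community bootstrap", {
  study <- generate_study(validation_config(40L), seed = 24)
  net <- study$network
  str <- study$truth$structure
  fit <- suppressMessages(spillover_ipw(net, str, ~ x_bin + x_age,
                                        alphas = 0.5, pairs = cbind(0.6, 0.2)))
  est <- fit$estimates
  ## nonparametric bootstrap resampling whole communities
  set.seed(31)
  B <- 300L
  memb <- str$assignment[net$records$.id]
  labs <- unique(memb)
  boot <- matrix(NA_real_, B, nrow(est))
  for (b in seq_len(B)) {
    pick <- sample(labs, length(labs), replace = TRUE)
    rows <- unlist(lapply(seq_along(pick), function(i)
      which(memb == pick[i])))
    newlab <- rep(seq_along(pick), times = vapply(pick, function(l)
      sum(memb == l), 0L))
    rb <- net$records[rows, , drop = FALSE]
    fb <- tryCatch(suppressMessages(netspill:::ipw_core(
      rb, newlab, ~ x_bin + x_age, 0.5, cbind(0.6, 0.2), NULL, 21L)),
      error = function(e) NULL)
    if (!is.null(fb)) boot[b, ] <- fb$estimates$estimate
  }
  bse <- apply(boot, 2L, sd, na.rm = TRUE)
  ## within 20% relative on every effect
  expect_true(all(abs(fit$estimates$se - bse) / bse < 0.20))
})

test_that("weight trimming drops extreme communities and is a no-op otherwise", {
  study <- generate_study(validation_config(20L), seed = 25)
  fit <- suppressMessages(
    spillover_ipw(study$network, study$truth$structure, ~ x_bin + x_age,
                  alphas = 0.5, pairs = cbind(0.6, 0.2)))
  w <- community_weights(fit)
  ## no weights outside generous bounds: estimates unchanged
  t0 <- trim_extreme(fit, low = 0, high = Inf)
  expect_equal(t0$estimates$estimate, fit$estimates$estimate,
               tolerance = 1e-12)
  expect_length(t0$trim$dropped, 0)
  ## force trimming at the observed median: communities actually dropped
  med <- stats::median(w$weight)
  t1 <- trim_extreme(fit, low = med, high = Inf)
  expect_gt(length(t1$trim$dropped), 0)
  expect_lt(t1$N, fit$N)
})
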
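#' Configuration for a synthetic network study
#'
#' Describes the generative law of a synthetic risk-network study with known
#' ground truth: a planted-partition graph (communities as blocks), two
#' confounders (a binary covariate and a standard-normal "age-like"
#' covariate, both entering treatment and outcome models), a treatment
#' assigned by a mixed-effects logit with community random intercept, and an
#' outcome following stratified interference — its law depends on a
#' participant's own treatment and on the treated proportion among the other
#' members of their community.
#'
#' Defaults emulate the motivating study's descriptives: 24 communities with
#' heterogeneous sizes 3-40 (log-normal, about 275 participants in total),
#' within-block edge probability 0.3 versus 0.004 between blocks, about 22%
#' treated, about 20% of outcomes missing at random (missingness depends on
#' treatment and the binary covariate, never on the outcome), and protective
#' direct and spillover effects on the log-odds scale.
#'
#' @param n_communities number of planted communities.
#' @param size_min,size_max,size_meanlog,size_sdlog community size law:
#'   `round(rlnorm(meanlog, sdlog))` clipped to `[size_min, size_max]`.
#' @param sizes optional explicit community sizes (overrides the size law).
#' @param p_within,p_between edge probabilities inside and between blocks.
#' @param treat_intercept,treat_beta,sigma_b treatment model
#'   \eqn{\mathrm{logit} P(A=1) = \theta_0 + \theta^T x + b_i},
#'   \eqn{b_i \sim N(0, \sigma_b^2)}. `treat_beta` is named `(x_bin, x_age)`.
#' @param out_intercept,beta_d,beta_s,out_beta outcome model
#'   \eqn{\mathrm{logit} P(Y=1) = \beta_0 + \beta_d A + \beta_s \rho_{-j} +
#'   \beta^T x}, where \eqn{\rho_{-j}} is the treated proportion among the
#'   other community members (0 for a singleton).
#' @param miss_rate_intercept,miss_beta_a,miss_beta_x MAR outcome
#'   missingness \eqn{\mathrm{logit} P(Y\ \mathrm{missing}) = m_0 + m_a A +
#'   m_x x_{bin}}; set `miss_rate_intercept = -Inf` for complete outcomes.
#' @param p_cov_missing MCAR missingness rate for the binary covariate.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_communities = 24L,
                             size_min = 3L, size_max = 40L,
                             size_meanlog = 2.15, size_sdlog = 0.75,
                             sizes = NULL,
                             p_within = 0.3, p_between = 0.004,
                             treat_intercept = -1.6,
                             treat_beta = c(x_bin = 0.5, x_age = 0.3),
                             sigma_b = 0.5,
                             out_intercept = 0.9,
                             beta_d = -1.0, beta_s = -1.0,
                             out_beta = c(x_bin = 0.5, x_age = 0.3),
                             miss_rate_intercept = -1.8,
                             miss_beta_a = 0.5, miss_beta_x = 0.5,
                             p_cov_missing = 0) {
  stopifnot(p_within > p_between, p_within <= 1, p_between >= 0,
            size_min >= 1L, sigma_b >= 0)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic network study with known ground truth
#'
#' Draws a study from a [synthetic_config()]: planted-partition graph (any
#' isolated node is attached to a random member of its own block so the
#' network has no degree-0 nodes), covariates, community random intercepts,
#' treatments, outcomes under stratified interference, and MAR outcome
#' missingness.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; the same seed reproduces the study exactly.
#' @return Object of class `synthetic_study`: `network` (a [risk_network()]),
#'   `truth` (the planted [community_structure()], random intercepts, full
#'   outcome vector before missingness), `config`, `seed`.
#' @export
generate_study <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    sizes <- config$sizes
    if (is.null(sizes)) {
      sizes <- pmin(pmax(round(stats::rlnorm(config$n_communities,
                                             config$size_meanlog,
                                             config$size_sdlog)),
                         config$size_min), config$size_max)
    }
    n <- sum(sizes)
    block <- rep(seq_along(sizes), sizes)
    ids <- sprintf("p%03d", seq_len(n))

    ## planted-partition edges
    pairs_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    pairs_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
    same <- block[pairs_i] == block[pairs_j]
    p_edge <- ifelse(same, config$p_within, config$p_between)
    keep <- stats::runif(length(p_edge)) < p_edge
    e1 <- pairs_i[keep]; e2 <- pairs_j[keep]
    ## attach isolated nodes to a random member of their own block
    deg <- tabulate(c(e1, e2), nbins = n)
    for (v in which(deg == 0L)) {
      others <- setdiff(which(block == block[v]), v)
      if (!length(others))
        stop("isolated singleton block; increase sizes or p_within")
      u <- others[sample.int(length(others), 1L)]
      e1 <- c(e1, min(u, v)); e2 <- c(e2, max(u, v))
      deg[c(u, v)] <- deg[c(u, v)] + 1L
    }

    x_bin <- stats::rbinom(n, 1L, 0.5)
    x_age <- stats::rnorm(n)
    b <- stats::rnorm(length(sizes), 0, config$sigma_b)
    eta_a <- config$treat_intercept + config$treat_beta[["x_bin"]] * x_bin +
      config$treat_beta[["x_age"]] * x_age + b[block]
    A <- stats::rbinom(n, 1L, expit(eta_a))

    treated_in_block <- rowsum(A, block)[, 1L]
    cov_others <- ifelse(sizes[block] > 1L,
                         (treated_in_block[block] - A) / (sizes[block] - 1L), 0)
    eta_y <- config$out_intercept + config$beta_d * A +
      config$beta_s * cov_others +
      config$out_beta[["x_bin"]] * x_bin + config$out_beta[["x_age"]] * x_age
    Y_full <- stats::rbinom(n, 1L, expit(eta_y))

    p_miss <- expit(config$miss_rate_intercept + config$miss_beta_a * A +
                    config$miss_beta_x * x_bin)
    miss <- stats::runif(n) < p_miss
    Y <- ifelse(miss, NA_integer_, Y_full)

    xb <- x_bin
    if (config$p_cov_missing > 0)
      xb[stats::runif(n) < config$p_cov_missing] <- NA_integer_

    attrs <- data.frame(id = ids, treatment = A, outcome = Y,
                        x_bin = xb, x_age = x_age,
                        stringsAsFactors = FALSE)
    edges <- data.frame(from = ids[e1], to = ids[e2],
                        stringsAsFactors = FALSE)
    net <- risk_network(edges, attrs, covariates = c("x_bin", "x_age"),
                        drop_isolates = FALSE)
    assignment <- stats::setNames(block, ids)[network_ids(net)]
    truth <- list(structure = community_structure(assignment, method = "given",
                                                  network = net),
                  b = b, sizes = sizes,
                  outcome_full = stats::setNames(Y_full, ids),
                  x_bin_full = stats::setNames(x_bin, ids))
    structure(list(network = net, truth = truth, config = config,
                   seed = seed),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic network study (seed ",
      if (is.null(x$seed)) "unset" else x$seed, ")\n", sep = "")
  print(x$network)
  cat("  planted communities:", x$truth$structure$N, "\n")
  invisible(x)
}

#' True counterfactual effects of a synthetic study
#'
#' Computes the study's true direct/spillover/total/overall risk differences
#' under Bernoulli allocation, conditional on the realized covariates and
#' community sizes. Because the outcome law depends on others' treatments
#' only through the treated count among the other members, the average over
#' counterfactual treatment vectors reduces to a binomial sum, so
#' `method = "exact"` enumerates it exactly for any community size;
#' `method = "mc"` instead draws `reps` counterfactual vectors per community
#' (independent cross-check, with Monte-Carlo standard errors).
#'
#' Communities of size 1 are excluded, matching the estimator.
#'
#' @param study a [generate_study()] result.
#' @param alphas coverages for the direct effect.
#' @param pairs two-column matrix of (alpha, alpha_prime) contrasts.
#' @param method `"exact"` (default) or `"mc"`.
#' @param reps Monte-Carlo replicates for `method = "mc"`.
#' @param seed seed for `method = "mc"`.
#' @return Data frame like a [spillover_ipw()] estimates table:
#'   effect, alpha, alpha_prime, truth (and `mc_se` for `method = "mc"`).
#' @export
true_effects <- function(study, alphas = c(0.2, 0.4, 0.6),
                         pairs = default_pairs(),
                         method = c("exact", "mc"), reps = 20000L,
                         seed = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  method <- match.arg(method)
  check_alpha(alphas)
  pairs <- validate_pairs(pairs)
  cfg <- study$config
  net <- study$network
  memb <- study$truth$structure$assignment[network_ids(net)]
  rec <- net$records
  x_bin <- study$truth$x_bin_full[rec$.id]  # pre-missingness covariate
  etax <- cfg$out_intercept + cfg$out_beta[["x_bin"]] * x_bin +
    cfg$out_beta[["x_age"]] * rec$x_age
  sizes <- table(memb)
  keep <- sizes[as.character(memb)] > 1L
  memb <- memb[keep]; etax <- etax[keep]
  fc <- as.integer(factor(memb))
  n_i <- as.integer(table(fc))
  N <- max(fc)

  ## per-participant conditional mean outcome given own arm a and s treated
  ## among the n-1 others: expit(etax + beta_d a + beta_s s/(n-1))
  pbar <- function(al) {
    y1 <- y0 <- numeric(length(etax))
    if (method == "exact") {
      for (i in seq_len(N)) {
        idx <- which(fc == i)
        nm1 <- n_i[i] - 1L
        s <- 0:nm1
        w <- stats::dbinom(s, nm1, al)
        rho <- s / nm1
        y1[idx] <- vapply(etax[idx], function(e)
          sum(w * expit(e + cfg$beta_d + cfg$beta_s * rho)), 0)
        y0[idx] <- vapply(etax[idx], function(e)
          sum(w * expit(e + cfg$beta_s * rho)), 0)
      }
    } else {
      for (i in seq_len(N)) {
        idx <- which(fc == i)
        nm1 <- n_i[i] - 1L
        s <- stats::rbinom(reps, nm1, al)
        rho <- s / nm1
        y1[idx] <- vapply(etax[idx], function(e)
          mean(expit(e + cfg$beta_d + cfg$beta_s * rho)), 0)
        y0[idx] <- vapply(etax[idx], function(e)
          mean(expit(e + cfg$beta_s * rho)), 0)
      }
    }
    list(y1 = y1, y0 = y0)
  }
  ## population means: average within community, then across communities
  popmean <- function(v) mean(rowsum(v, fc)[, 1L] / n_i)

  with_seed(seed, {
    need <- sort(unique(c(alphas, c(pairs))))
    tab <- lapply(need, pbar)
    names(tab) <- as.character(need)
    mu1 <- vapply(tab, function(t) popmean(t$y1), 0)
    mu0 <- vapply(tab, function(t) popmean(t$y0), 0)
    mum <- vapply(seq_along(need),
                  function(k) need[k] * mu1[k] + (1 - need[k]) * mu0[k], 0)
    names(mum) <- names(mu1)
    rows <- list()
    for (al in alphas) {
      a <- as.character(al)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = "direct", alpha = al, alpha_prime = NA_real_,
        truth = mu1[[a]] - mu0[[a]], row.names = NULL)
    }
    for (r in seq_len(nrow(pairs))) {
      a <- as.character(pairs[r, 1L]); ap <- as.character(pairs[r, 2L])
      rows[[length(rows) + 1L]] <- data.frame(
        effect = c("spillover", "total", "overall"),
        alpha = pairs[r, 1L], alpha_prime = pairs[r, 2L],
        truth = c(mu0[[a]] - mu0[[ap]], mu1[[a]] - mu0[[ap]],
                  mum[[a]] - mum[[ap]]), row.names = NULL)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
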
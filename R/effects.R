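#' Allocation-strategy probabilities
#'
#' Under a Bernoulli allocation strategy with coverage `alpha`, each
#' participant is independently assigned treatment with probability `alpha`.
#' `policy_prob()` is the probability of a full treatment vector,
#' \eqn{\prod_j \alpha^{a_j}(1-\alpha)^{1-a_j}}; `policy_prob_excluding()`
#' omits position `j` (the empty product for a single-member community is 1).
#' Products are accumulated in log space.
#'
#' @param a binary treatment vector.
#' @param alpha coverage probability in (0, 1).
#' @param j index to exclude.
#' @return A probability.
#' @export
policy_prob <- function(a, alpha) {
  stopifnot(length(a) >= 1L, all(a %in% 0:1))
  check_alpha(alpha)
  exp(sum(a) * log(alpha) + sum(1 - a) * log1p(-alpha))
}

#' @rdname policy_prob
#' @export
policy_prob_excluding <- function(a, j, alpha) {
  stopifnot(j >= 1L, j <= length(a))
  if (length(a) == 1L) return(1)
  policy_prob(a[-j], alpha)
}

check_alpha <- function(alpha) {
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie strictly in (0, 1)")
  invisible(alpha)
}

#' Group-level IPW potential-outcome estimators
#'
#' Single-community building blocks of the population estimators:
#' `group_ipw_mean()` is the arm-specific community estimate
#' \eqn{\sum_j \pi_i(A_{i,-j};\alpha)\,1\{A_{ij}=a\}\,Y_{ij} / (n_i f_i)}
#' and `group_ipw_marginal()` the marginal estimate
#' \eqn{\sum_j \pi_i(A_i;\alpha)\,Y_{ij} / (n_i f_i)}, where \eqn{f_i} is the
#' community-level propensity score of the observed treatment vector.
#'
#' @param A observed binary treatment vector of the community.
#' @param Y observed binary outcome vector (no missing values).
#' @param f community-level propensity score in (0, 1].
#' @param alpha allocation coverage in (0, 1).
#' @param arm treatment arm, 0 or 1.
#' @return A nonnegative scalar.
#' @export
group_ipw_mean <- function(A, Y, f, alpha, arm) {
  stopifnot(length(A) == length(Y), arm %in% 0:1, f > 0)
  if (anyNA(Y)) stop("outcomes must be non-missing (impute first)")
  check_alpha(alpha)
  n <- length(A)
  lp_full <- sum(A) * log(alpha) + sum(1 - A) * log1p(-alpha)
  lp_minus <- lp_full - ifelse(A == 1, log(alpha), log1p(-alpha))
  sum(exp(lp_minus - log(f)) * (A == arm) * Y) / n
}

#' @rdname group_ipw_mean
#' @export
group_ipw_marginal <- function(A, Y, f, alpha) {
  stopifnot(length(A) == length(Y), f > 0)
  if (anyNA(Y)) stop("outcomes must be non-missing (impute first)")
  check_alpha(alpha)
  n <- length(A)
  lp_full <- sum(A) * log(alpha) + sum(1 - A) * log1p(-alpha)
  exp(lp_full - log(f)) * sum(Y) / n
}

#' Estimate direct, spillover, total and overall effects by IPW
#'
#' The main fitting function. Defines interference sets by the supplied
#' community structure, computes community-level propensity scores from a
#' mixed-effects logit of treatment on measured confounders (fitted here
#' unless a converged model or known scores are supplied), and estimates the
#' four causal risk differences under Bernoulli allocation strategies:
#' direct \eqn{DE(\alpha)} (treated vs untreated at coverage \eqn{\alpha}),
#' spillover \eqn{SE(\alpha,\alpha')} (untreated at \eqn{\alpha} vs
#' \eqn{\alpha'}), total \eqn{TE(\alpha,\alpha') = DE(\alpha) +
#' SE(\alpha,\alpha')}, and overall \eqn{OE(\alpha,\alpha')} (marginal
#' contrast). Standard errors are M-estimation sandwich estimates treating
#' communities as independent units and stacking the propensity-score
#' equations with the target means (so they account for weight estimation);
#' confidence intervals are 95% Wald (multiplier 1.96).
#'
#' Singleton communities are excluded (no spillover is possible in them)
#' with a message.
#'
#' @param network a [risk_network()] whose outcomes are fully observed
#'   (impute first; see [impute_outcome()]).
#' @param structure a [community_structure()] on the network.
#' @param propensity a right-hand-side formula of confounders
#'   (e.g. `~ age + nationality`), or a converged [mixed_logit()] fit of
#'   treatment. Ignored when `known_f` is given.
#' @param alphas coverages for the direct effect (default 0.2, 0.4, 0.6).
#' @param pairs two-column matrix of (alpha, alpha_prime) rows with
#'   alpha > alpha_prime for spillover/total/overall (default (0.6,0.2),
#'   (0.4,0.2), (0.6,0.4)).
#' @param known_f optional known community-level propensity scores (named
#'   numeric vector, names = community labels). When supplied the weights
#'   are treated as known and the sandwich reduces to the i.i.d.
#'   per-community form.
#' @param nodes quadrature nodes for the propensity integration.
#' @return Object of class `spillover_ipw` with `estimates` (one row per
#'   effect: effect, alpha, alpha_prime, estimate, se, lower, upper), `mu`
#'   (population average potential outcomes), `vcov_mu`, `weights`
#'   (community IPWs per alpha), `propensity` (the fitted model, if any),
#'   `n_excluded_singletons`, and the inputs needed by [trim_extreme()].
#' @examples
#' study <- generate_study(synthetic_config(n_communities = 10), seed = 1)
#' fit <- spillover_ipw(study$network, study$truth$structure, ~ x_bin + x_age)
#' fit
#' @export
spillover_ipw <- function(network, structure, propensity = NULL,
                          alphas = c(0.2, 0.4, 0.6),
                          pairs = default_pairs(), known_f = NULL,
                          nodes = 21L) {
  stopifnot(inherits(network, "risk_network"))
  check_alpha(alphas)
  pairs <- validate_pairs(pairs)
  memb <- as_membership(structure, network)
  rec <- network$records
  if (anyNA(rec$.outcome))
    stop("network has missing outcomes; run impute_outcome() first")
  comm_lab <- memb[rec$.id]
  sizes <- table(comm_lab)
  singletons <- names(sizes)[sizes == 1L]
  if (length(singletons)) {
    message(length(singletons),
            " singleton communit", if (length(singletons) > 1) "ies" else "y",
            " excluded from estimation (no spillover possible)")
    keep <- !(comm_lab %in% singletons)
    rec <- rec[keep, , drop = FALSE]
    comm_lab <- comm_lab[keep]
  }
  fit <- ipw_core(rec, comm_lab, propensity, alphas, pairs, known_f, nodes)
  fit$n_excluded_singletons <- length(singletons)
  fit$structure_method <-
    if (inherits(structure, "community_structure")) structure$method else "given"
  fit
}

default_pairs <- function() {
  cbind(alpha = c(0.6, 0.4, 0.6), alpha_prime = c(0.2, 0.2, 0.4))
}

validate_pairs <- function(pairs) {
  pairs <- matrix(as.numeric(pairs), ncol = 2L,
                  dimnames = list(NULL, c("alpha", "alpha_prime")))
  check_alpha(c(pairs))
  if (any(pairs[, 1L] <= pairs[, 2L]))
    stop("each pair must satisfy alpha > alpha_prime")
  pairs
}

## Core estimator on assembled records; `rec` needs .treatment/.outcome and
## covariate columns, `comm_lab` community labels aligned to rows.
ipw_core <- function(rec, comm_lab, propensity, alphas, pairs, known_f,
                     nodes) {
  fc <- factor(comm_lab)
  comm <- as.integer(fc)
  N <- nlevels(fc)
  if (N < 2L) stop("need at least 2 communities")
  A <- rec$.treatment
  Y <- rec$.outcome
  n_i <- as.integer(table(comm))

  model <- NULL
  if (is.null(known_f)) {
    if (inherits(propensity, "mixed_logit")) {
      model <- propensity
      recf <- rec
      for (nm in names(recf))
        if (is.character(recf[[nm]]))
          recf[[nm]] <- factor(recf[[nm]], levels = sort(unique(recf[[nm]])))
      mf <- stats::model.frame(model$terms, recf,
                               na.action = stats::na.fail,
                               xlev = model$xlevels)
      Xr <- stats::model.matrix(model$terms, mf)
      yr <- stats::model.response(mf)
    } else if (inherits(propensity, "formula")) {
      rhs <- if (length(propensity) == 3L) propensity[c(1, 3)] else propensity
      fml <- stats::as.formula(paste(".treatment ~",
                                     deparse(rhs[[length(rhs)]])))
      model <- mixed_logit(fml, rec, comm_lab, nodes = nodes)
      Xr <- model$X
      yr <- model$y
    } else {
      stop("propensity must be a formula, a mixed_logit fit, or supply known_f")
    }
    log_f <- agh_log_f(yr, drop(Xr %*% model$theta), comm, model$sigma, nodes)
  } else {
    f <- known_f[match(levels(fc), names(known_f))]
    if (anyNA(f)) stop("known_f missing for community(ies): ",
                       paste(levels(fc)[is.na(f)], collapse = ", "))
    if (any(f <= 0)) stop("known_f must be positive")
    log_f <- log(unname(f))
  }

  ## community-level group estimates per coverage (union of direct grid and
  ## pair coverages)
  alpha_grid <- sort(unique(c(alphas, c(pairs))))
  K <- length(alpha_grid)
  Yhat1 <- Yhat0 <- Yhatm <- matrix(0, N, K)
  sumA <- rowsum(A, comm)[, 1L]
  sumY <- rowsum(Y, comm)[, 1L]
  for (k in seq_len(K)) {
    al <- alpha_grid[k]
    lp_full <- sumA * log(al) + (n_i - sumA) * log1p(-al)
    lp_minus <- lp_full[comm] - ifelse(A == 1, log(al), log1p(-al))
    w_minus <- exp(lp_minus - log_f[comm])
    Yhat1[, k] <- rowsum(w_minus * (A == 1) * Y, comm)[, 1L] / n_i
    Yhat0[, k] <- rowsum(w_minus * (A == 0) * Y, comm)[, 1L] / n_i
    Yhatm[, k] <- exp(lp_full - log_f) * sumY / n_i
  }
  ## target stack order: (mu1, mu0, mum) x alpha
  targets <- cbind(Yhat1, Yhat0, Yhatm)[, rep(seq_len(K), each = 3L) +
                                          c(0L, K, 2L * K), drop = FALSE]
  tnames <- paste0(rep(c("mu1", "mu0", "mum"), K), "_",
                   rep(alpha_grid, each = 3L))
  colnames(targets) <- tnames
  mu <- colMeans(targets)

  ## sandwich variance, communities as i.i.d. units
  psi_t <- sweep(targets, 2L, mu)        # N x T
  if (is.null(known_f) && !is.null(model)) {
    phi <- c(model$theta, if (model$sigma > 0) model$sigma)
    has_sigma <- model$sigma > 0
    logf_fun <- function(p) {
      sig <- if (has_sigma) max(p[length(p)], 0) else 0
      th <- if (has_sigma) p[-length(p)] else p
      agh_log_f(yr, drop(Xr %*% th), comm, sig, nodes)
    }
    S <- num_jacobian(logf_fun, phi)     # N x p scores of log f_i
    Htot <- num_hessian(function(p) sum(logf_fun(p)), phi)
    p <- length(phi)
    Tt <- ncol(targets)
    A11 <- -Htot / N
    A21 <- crossprod(targets, S) / N     # T x p:  (1/N) sum Yhat_i s_i^T
    bread <- rbind(cbind(A11, matrix(0, p, Tt)),
                   cbind(A21, diag(Tt)))
    psi <- cbind(S, psi_t)
    B <- crossprod(psi) / N
    if (rcond(bread) < 1e-12)
      stop("singular bread matrix in sandwich variance (condition number ",
           format(1 / rcond(bread), digits = 3), ")")
    Ainv <- solve(bread)
    V <- Ainv %*% B %*% t(Ainv) / N
    vcov_mu <- V[p + seq_len(Tt), p + seq_len(Tt), drop = FALSE]
  } else {
    vcov_mu <- crossprod(psi_t) / N^2
  }
  dimnames(vcov_mu) <- list(tnames, tnames)

  ## effect contrasts
  idx <- function(kind, al) {
    i <- match(paste0(kind, "_", al), tnames)
    stopifnot(!anyNA(i))
    i
  }
  rows <- list()
  for (al in alphas) {
    l <- numeric(length(tnames))
    l[idx("mu1", al)] <- 1; l[idx("mu0", al)] <- -1
    rows[[length(rows) + 1L]] <- effect_row("direct", al, NA, l, mu, vcov_mu)
  }
  for (r in seq_len(nrow(pairs))) {
    al <- pairs[r, 1L]; alp <- pairs[r, 2L]
    l <- numeric(length(tnames)); l[idx("mu0", al)] <- 1; l[idx("mu0", alp)] <- -1
    rows[[length(rows) + 1L]] <- effect_row("spillover", al, alp, l, mu, vcov_mu)
    l <- numeric(length(tnames)); l[idx("mu1", al)] <- 1; l[idx("mu0", alp)] <- -1
    rows[[length(rows) + 1L]] <- effect_row("total", al, alp, l, mu, vcov_mu)
    l <- numeric(length(tnames)); l[idx("mum", al)] <- 1; l[idx("mum", alp)] <- -1
    rows[[length(rows) + 1L]] <- effect_row("overall", al, alp, l, mu, vcov_mu)
  }
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL

  weights <- community_ipw_weights(sumA, n_i, log_f, alpha_grid, levels(fc))

  structure(list(estimates = estimates, mu = mu, vcov_mu = vcov_mu,
                 weights = weights, propensity = model,
                 alphas = alphas, pairs = pairs, nodes = nodes,
                 known_f = known_f,
                 N = N, n = length(A), sizes = n_i,
                 community_labels = levels(fc),
                 group_estimates = targets,
                 rec = rec, comm_lab = comm_lab,
                 propensity_spec = if (inherits(propensity, "formula"))
                   propensity else NULL,
                 n_excluded_singletons = 0L),
            class = "spillover_ipw")
}

effect_row <- function(effect, alpha, alpha_prime, l, mu, vcov_mu) {
  est <- sum(l * mu)
  se <- sqrt(drop(l %*% vcov_mu %*% l))
  data.frame(effect = effect, alpha = alpha, alpha_prime = alpha_prime,
             estimate = est, se = se,
             lower = est - 1.96 * se, upper = est + 1.96 * se,
             stringsAsFactors = FALSE)
}

community_ipw_weights <- function(sumA, n_i, log_f, alphas, labels) {
  out <- lapply(alphas, function(al) {
    lp_full <- sumA * log(al) + (n_i - sumA) * log1p(-al)
    data.frame(community = labels, n = n_i, alpha = al,
               weight = exp(lp_full - log_f), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Community-level inverse probability weights
#'
#' The IPW of community \eqn{i} at coverage \eqn{\alpha} is
#' \eqn{\pi_i(A_i;\alpha)/f(A_i|X_i)}: the allocation-strategy probability of
#' the observed treatment vector over its estimated propensity.
#'
#' @param fit a [spillover_ipw()] object.
#' @return Data frame: community, n, alpha, weight.
#' @export
community_weights <- function(fit) {
  stopifnot(inherits(fit, "spillover_ipw"))
  fit$weights
}

#' Extreme-weight sensitivity analysis
#'
#' Flags communities whose IPW is extreme (below `low` or above `high`) at
#' any of the fitted coverages, removes them, and re-estimates all effects
#' (including refitting the propensity model) on the retained communities.
#'
#' @param fit a [spillover_ipw()] object fitted with a formula (so the
#'   propensity model can be refitted on the retained set) or `known_f`.
#' @param low,high trimming bounds on the community IPW (defaults 0.001 and
#'   `Inf`).
#' @return A new `spillover_ipw` object with a `$trim` element recording the
#'   bounds and the dropped communities. If no community is extreme the
#'   estimates are identical to `fit`'s.
#' @export
trim_extreme <- function(fit, low = 0.001, high = Inf) {
  stopifnot(inherits(fit, "spillover_ipw"))
  w <- fit$weights
  extreme <- unique(w$community[w$weight < low | w$weight > high])
  keep <- !(fit$comm_lab %in% extreme)
  if (!any(keep)) stop("trimming removed every community")
  prop <- if (!is.null(fit$propensity_spec)) fit$propensity_spec else NULL
  kf <- fit$known_f
  if (is.null(prop) && is.null(kf))
    stop("refit requires the original propensity formula or known_f")
  out <- ipw_core(fit$rec[keep, , drop = FALSE], fit$comm_lab[keep],
                  prop, fit$alphas, fit$pairs, kf, fit$nodes)
  out$trim <- list(low = low, high = high, dropped = extreme)
  out
}

#' @export
print.spillover_ipw <- function(x, digits = 3, ...) {
  cat("IPW spillover analysis: ", x$N, " communities, ", x$n,
      " participants", sep = "")
  if (x$n_excluded_singletons)
    cat(" (", x$n_excluded_singletons, " singleton(s) excluded)", sep = "")
  cat("\n")
  if (!is.null(x$propensity))
    cat("Propensity: mixed logit, sigma_b = ",
        format(x$propensity$sigma, digits = 3), "\n", sep = "")
  else cat("Propensity: known (supplied) community-level scores\n")
  if (!is.null(x$trim))
    cat("Trimmed communities with IPW outside [", x$trim$low, ", ",
        x$trim$high, "]: ", length(x$trim$dropped), " dropped\n", sep = "")
  est <- x$estimates
  est$` ` <- sprintf("%+.*f (%.*f, %.*f)", digits, est$estimate,
                     digits, est$lower, digits, est$upper)
  lab <- ifelse(is.na(est$alpha_prime),
                sprintf("%s (%.2f, %.2f)", est$effect, est$alpha, est$alpha),
                sprintf("%s (%.2f, %.2f)", est$effect, est$alpha,
                        est$alpha_prime))
  cat("\nRisk differences (95% Wald CI):\n")
  for (i in seq_len(nrow(est))) cat(sprintf("  %-22s %s\n", lab[i], est$` `[i]))
  invisible(x)
}

#' @export
summary.spillover_ipw <- function(object, ...) {
  out <- object$estimates
  attr(out, "N") <- object$N
  attr(out, "mu") <- object$mu
  class(out) <- c("summary.spillover_ipw", "data.frame")
  out
}

#' @export
print.summary.spillover_ipw <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.spillover_ipw <- function(object, ...) {
  est <- object$estimates
  nm <- ifelse(is.na(est$alpha_prime),
               sprintf("%s(%g)", est$effect, est$alpha),
               sprintf("%s(%g,%g)", est$effect, est$alpha, est$alpha_prime))
  stats::setNames(est$estimate, nm)
}

#' @export
confint.spillover_ipw <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimates
  out <- cbind(est$estimate - z * est$se, est$estimate + z * est$se)
  rownames(out) <- names(coef(object))
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
plot.spillover_ipw <- function(x, ...) {
  est <- x$estimates
  k <- nrow(est)
  lab <- names(coef(x))
  old <- graphics::par(mar = c(4, 9, 2, 1)); on.exit(graphics::par(old))
  graphics::plot(est$estimate, seq_len(k), xlim = range(est$lower, est$upper, 0),
                 ylim = c(0.5, k + 0.5), yaxt = "n", pch = 19,
                 xlab = "Risk difference", ylab = "", ...)
  graphics::segments(est$lower, seq_len(k), est$upper, seq_len(k))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(k), labels = lab, las = 1, cex.axis = 0.8)
  invisible(x)
}
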
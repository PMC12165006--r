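## Mixed-effects logit with a community random intercept, fitted by direct
## maximization of the adaptive Gauss-Hermite marginal likelihood, and the
## community-level propensity score: the probability of a community's
## observed treatment vector given covariates, integrating the random
## intercept against N(0, sigma_b^2).

## Gauss-Hermite rule (weight exp(-t^2)); cached per node count.
gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(k) {
  key <- as.character(k)
  if (is.null(gh_cache[[key]])) gh_cache[[key]] <- pracma::gaussHermite(k)
  gh_cache[[key]]
}

## Conditional modes of the random intercept given (eta, sigma): vectorized
## Newton iteration on the concave per-community log integrand.
## y: 0/1 vector; eta: fixed-effect linear predictor; comm: integer community
## index 1..N. Returns list(mode, neg_curv) with per-community values.
re_modes <- function(y, eta, comm, sigma, nmax = 50L, tol = 1e-10) {
  N <- max(comm)
  b <- numeric(N)
  for (it in seq_len(nmax)) {
    h <- expit(eta + b[comm])
    gp <- rowsum(y - h, comm, reorder = TRUE)[, 1L] - b / sigma^2
    gpp <- -rowsum(h * (1 - h), comm, reorder = TRUE)[, 1L] - 1 / sigma^2
    step <- gp / gpp
    b <- b - step
    if (max(abs(step)) < tol) break
  }
  list(mode = b, neg_curv = -gpp)
}

## log f_i, the community-level propensity score, for every community:
## adaptive Gauss-Hermite quadrature with `nodes` points centered/scaled at
## the conditional mode. sigma = 0 degenerates to the plain Bernoulli product.
agh_log_f <- function(y, eta, comm, sigma, nodes = 21L) {
  comm <- as.integer(comm)
  N <- max(comm)
  if (sigma < 1e-8) {
    return(unname(rowsum(bernoulli_loglik(y, eta), comm, reorder = TRUE)[, 1L]))
  }
  md <- re_modes(y, eta, comm, sigma)
  tau <- 1 / sqrt(md$neg_curv)
  rule <- gh_rule(nodes)
  L <- matrix(0, N, nodes)   # log integrand at each node
  for (k in seq_len(nodes)) {
    bk <- md$mode + sqrt(2) * tau * rule$x[k]
    L[, k] <- rowsum(bernoulli_loglik(y, eta + bk[comm]), comm,
                     reorder = TRUE)[, 1L] +
      stats::dnorm(bk, 0, sigma, log = TRUE)
  }
  L <- sweep(L, 2L, log(rule$w) + rule$x^2, "+")
  mx <- apply(L, 1L, max)
  unname(log(sqrt(2) * tau) + mx + log(rowSums(exp(L - mx))))
}

#' Fit a mixed-effects logistic regression with a community random intercept
#'
#' Maximizes the marginal likelihood obtained by integrating a normal random
#' intercept \eqn{b_i \sim N(0, \sigma_b^2)} out of a logistic model
#' \eqn{\mathrm{logit}\,P(y_{ij}=1) = x_{ij}^T\theta + b_i}, using adaptive
#' Gauss-Hermite quadrature. This marginal likelihood is exactly the product
#' over communities of the community-level propensity scores, so the fitted
#' object feeds directly into [community_propensity()] and the IPW sandwich
#' variance.
#'
#' @param formula model formula for the binary response (e.g.
#'   `treatment ~ age + nationality`).
#' @param data data frame holding the response and covariates. Character
#'   columns are treated as factors with sorted levels (first level is the
#'   reference).
#' @param community community label for each row (vector or the name of a
#'   column in `data`).
#' @param nodes number of quadrature nodes (default 21).
#' @param start optional starting values `c(theta, sigma)`.
#' @return Object of class `mixed_logit` with elements `theta`, `sigma`
#'   (\eqn{\hat\sigma_b \ge 0}), `loglik`, `converged`, `terms`, plus the
#'   design internals used by downstream estimators.
#' @seealso [community_propensity()], [spillover_ipw()]
#' @export
mixed_logit <- function(formula, data, community, nodes = 21L, start = NULL) {
  if (is.character(community) && length(community) == 1L)
    community <- data[[community]]
  stopifnot(length(community) == nrow(data))
  data <- as.data.frame(data)
  for (nm in names(data))
    if (is.character(data[[nm]]))
      data[[nm]] <- factor(data[[nm]], levels = sort(unique(data[[nm]])))
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!all(y %in% 0:1)) stop("response must be binary 0/1")
  if (length(unique(y)) < 2L) stop("response is constant; model not identifiable")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  comm <- as.integer(factor(community))

  ## separation screen: a column that perfectly predicts the response makes
  ## the likelihood unbounded
  for (j in seq_len(ncol(X))[-1L]) {
    v <- X[, j]
    if (length(unique(v)) == 2L) {
      tab <- table(factor(v), factor(y, levels = 0:1))
      if (all(rowSums(tab > 0) == 1L) &&
          length(unique(apply(tab, 1L, which.max))) == 2L)
        stop("separation: column '", colnames(X)[j],
             "' perfectly predicts the response")
    }
  }

  negll <- function(par) {
    sigma <- max(par[length(par)], 0)
    eta <- drop(X %*% par[-length(par)])
    -sum(agh_log_f(y, eta, comm, sigma, nodes))
  }
  if (is.null(start)) {
    g0 <- stats::glm.fit(X, y, family = stats::binomial())
    if (any(abs(g0$coefficients) > 15))
      stop("separation suspected: column '",
           colnames(X)[which.max(abs(g0$coefficients))],
           "' has a diverging coefficient")
    start <- c(g0$coefficients, 0.5)
  }
  fit <- stats::optim(start, negll, method = "L-BFGS-B",
                      lower = c(rep(-Inf, ncol(X)), 0),
                      control = list(maxit = 500L))
  if (fit$convergence != 0)
    stop("mixed logit failed to converge (optim code ", fit$convergence, ")")
  theta <- fit$par[-length(fit$par)]
  names(theta) <- colnames(X)
  sigma <- max(fit$par[length(fit$par)], 0)
  if (sigma < 1e-6) sigma <- 0
  structure(list(theta = theta, sigma = sigma, loglik = -fit$value,
                 converged = TRUE, nodes = nodes,
                 formula = formula, terms = attr(mf, "terms"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 X = X, y = y, comm = comm,
                 community_levels = levels(factor(community))),
            class = "mixed_logit")
}

#' @export
print.mixed_logit <- function(x, ...) {
  cat("Mixed-effects logit (adaptive Gauss-Hermite,", x$nodes, "nodes)\n")
  cat("  log-likelihood:", format(x$loglik, digits = 6), "\n")
  cat("  sigma_b:", format(x$sigma, digits = 4), "\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' @export
coef.mixed_logit <- function(object, ...) object$theta

#' @export
logLik.mixed_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta) + 1, class = "logLik")
}

#' Model summary with standard errors from the observed information
#' @param object a [mixed_logit()] fit.
#' @param ... unused.
#' @export
summary.mixed_logit <- function(object, ...) {
  par <- c(object$theta, sigma_b = object$sigma)
  H <- num_hessian(function(p) {
    sigma <- max(p[length(p)], 0)
    sum(agh_log_f(object$y, drop(object$X %*% p[-length(p)]), object$comm,
                  sigma, object$nodes))
  }, par)
  se <- rep(NA_real_, length(par))
  ok <- tryCatch({
    v <- diag(solve(-H)); v[v < 0] <- NA; sqrt(v)
  }, error = function(e) se)
  out <- data.frame(term = names(par), estimate = unname(par),
                    se = unname(ok))
  class(out) <- c("summary.mixed_logit", "data.frame")
  out
}

## Central-difference Hessian (symmetrized); f scalar-valued.
num_hessian <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- 1e-4 * (abs(x) + 1)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- ej <- numeric(p); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * h[i] * h[j])
  }
  H
}

## Central-difference gradient of a vector-valued function (returns matrix
## rows = components of f's value, cols = parameters).
num_jacobian <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- 1e-6 * (abs(x) + 1)
  cols <- vector("list", p)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    cols[[i]] <- (f(x + ei) - f(x - ei)) / (2 * h[i])
  }
  do.call(cbind, cols)
}

#' Community-level propensity scores
#'
#' Evaluates, for each community, the probability of its observed treatment
#' vector given covariates: the per-member Bernoulli likelihood integrated
#' over the community's normal random intercept (adaptive Gauss-Hermite
#' quadrature at the model's node count). With \eqn{\sigma_b = 0} this is the
#' plain product of member-level probabilities.
#'
#' @param model a converged [mixed_logit()] fit of the treatment model.
#' @param newdata optional data frame + `community` to evaluate on different
#'   records; defaults to the fitting data.
#' @param community community labels matching `newdata`.
#' @return Data frame with one row per community: `community`, `n`,
#'   `f_value` in (0, 1], `log_f`, and `quadrature_nodes`.
#' @export
community_propensity <- function(model, newdata = NULL, community = NULL) {
  stopifnot(inherits(model, "mixed_logit"))
  if (!isTRUE(model$converged)) stop("propensity model did not converge")
  if (is.null(newdata)) {
    y <- model$y; X <- model$X; comm <- model$comm
    labels <- model$community_levels
  } else {
    for (nm in names(newdata))
      if (is.character(newdata[[nm]]))
        newdata[[nm]] <- factor(newdata[[nm]],
                                levels = sort(unique(newdata[[nm]])))
    mf <- stats::model.frame(model$terms, newdata, na.action = stats::na.fail,
                             xlev = model$xlevels)
    y <- stats::model.response(mf)
    X <- stats::model.matrix(model$terms, mf)
    fc <- factor(community)
    comm <- as.integer(fc)
    labels <- levels(fc)
  }
  log_f <- agh_log_f(y, drop(X %*% model$theta), comm, model$sigma,
                     model$nodes)
  if (any(log_f < log(1e-300)))
    stop("community propensity underflow (< 1e-300); consider smaller ",
         "communities or rescaled covariates")
  data.frame(community = labels,
             n = as.integer(table(comm)),
             f_value = exp(log_f),
             log_f = log_f,
             quadrature_nodes = model$nodes,
             stringsAsFactors = FALSE)
}

#' Screen candidate confounders for the propensity model
#'
#' Three-stage screen mirroring common propensity-model variable selection
#' practice: (1) drop variables with generalized variance inflation factor
#' above `vif_threshold` (largest first, recomputed after each drop);
#' (2) among pairs of categorical variables associated at chi-square
#' p < `alpha`, iteratively drop the variable involved in the most
#' significant pairs (ties broken by later position in `candidates`);
#' (3) drop variables producing an empty treatment-by-level cell or making
#' the mixed logit fail to converge.
#'
#' @param data data frame of participant records.
#' @param treatment name of the binary treatment column.
#' @param candidates ordered character vector of candidate covariate names
#'   (at least 2; order encodes a-priori preference, earlier = keep).
#' @param community community labels (vector or column name) for the
#'   stage-3 convergence check.
#' @param vif_threshold GVIF threshold, default 10.
#' @param alpha chi-square significance level, default 0.05.
#' @return List with `selected` (character vector) and `report` (data frame
#'   of drops with stage and reason).
#' @export
screen_covariates <- function(data, treatment, candidates, community,
                              vif_threshold = 10, alpha = 0.05) {
  stopifnot(length(candidates) >= 2L)
  if (is.character(community) && length(community) == 1L)
    community <- data[[community]]
  data <- as.data.frame(data)
  for (nm in candidates)
    if (is.character(data[[nm]]))
      data[[nm]] <- factor(data[[nm]], levels = sort(unique(data[[nm]])))
  report <- data.frame(variable = character(), stage = integer(),
                       reason = character(), stringsAsFactors = FALSE)
  drop_var <- function(v, stage, reason) {
    report <<- rbind(report, data.frame(variable = v, stage = stage,
                                        reason = reason))
    candidates <<- setdiff(candidates, v)
  }

  ## stage 1: generalized VIFs (Fox-Monette determinant formula)
  repeat {
    if (length(candidates) < 2L) break
    vifs <- gvif(data, candidates)
    if (all(vifs <= vif_threshold | is.na(vifs))) break
    vmax <- max(vifs, na.rm = TRUE)
    ## ties (e.g. exact duplicates): drop the later-listed candidate
    tied <- names(vifs)[!is.na(vifs) & vifs >= vmax * (1 - 1e-8)]
    worst <- tied[which.max(match(tied, candidates))]
    drop_var(worst, 1L, sprintf("GVIF %.1f > %.1f", vmax, vif_threshold))
  }

  ## stage 2: pairwise chi-square association among categorical candidates
  repeat {
    cats <- candidates[vapply(candidates, function(v)
      is.factor(data[[v]]) || length(unique(data[[v]])) <= 5L, TRUE)]
    if (length(cats) < 2L) break
    sig <- matrix(FALSE, length(cats), length(cats),
                  dimnames = list(cats, cats))
    for (i in seq_along(cats)) for (j in seq_len(i - 1L)) {
      p <- suppressWarnings(stats::chisq.test(
        table(data[[cats[i]]], data[[cats[j]]]))$p.value)
      if (!is.na(p) && p < alpha) sig[i, j] <- sig[j, i] <- TRUE
    }
    counts <- rowSums(sig)
    if (all(counts == 0)) break
    worst_n <- max(counts)
    ## ties: prefer dropping the later-listed candidate
    tied <- names(counts)[counts == worst_n]
    worst <- tied[which.max(match(tied, candidates))]
    drop_var(worst, 2L, sprintf("associated with %d other covariate(s), p < %.2f",
                                worst_n, alpha))
  }

  ## stage 3: empty treatment-by-level cells, then convergence
  a <- data[[treatment]]
  for (v in candidates) {
    if (is.factor(data[[v]]) && any(table(a, data[[v]]) == 0L))
      drop_var(v, 3L, "empty treatment-by-level cell")
  }
  repeat {
    if (length(candidates) == 0L) stop("all candidate covariates eliminated")
    fml <- stats::reformulate(candidates, response = treatment)
    ok <- tryCatch({
      mixed_logit(fml, data, community)
      TRUE
    }, error = function(e) FALSE)
    if (ok) break
    drop_var(candidates[length(candidates)], 3L,
             "mixed logit failed to converge")
  }
  list(selected = candidates, report = report)
}

## Generalized VIF per candidate from the correlation matrix of the
## intercept-free design (Fox & Monette 1992).
gvif <- function(data, candidates) {
  X <- stats::model.matrix(stats::reformulate(candidates), data)[, -1L, drop = FALSE]
  keep <- apply(X, 2L, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  R <- stats::cor(X)
  detR <- det(R)
  asg <- attr(stats::model.matrix(stats::reformulate(candidates), data),
              "assign")[-1L][keep]
  out <- vapply(seq_along(candidates), function(k) {
    idx <- which(asg == k)
    if (!length(idx) || length(idx) == ncol(X)) return(NA_real_)
    det(R[idx, idx, drop = FALSE]) *
      det(R[-idx, -idx, drop = FALSE]) / detR
  }, 0)
  names(out) <- candidates
  out
}
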
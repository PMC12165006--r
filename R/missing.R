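#' Iterative random-forest imputation of missing covariates
#'
#' Fills missing covariate cells without removing participants from the
#' network. Missing cells are initialized with the observed mode (categorical
#' or binary) or mean (numeric); covariates are then cycled in order of
#' increasing missingness, each refitted by a random forest on all other
#' covariates using rows where it was originally observed, and its missing
#' cells overwritten by forest predictions. Cycling stops when the change
#' criterion (missForest-style: normalized squared change for numeric,
#' proportion of changed categories for categorical) first rises, or after
#' `maxiter` sweeps. Observed cells are never altered.
#'
#' @param data data frame of participant records.
#' @param covariates character vector of covariate columns to complete.
#' @param ntree trees per forest (default 100).
#' @param maxiter maximum sweeps (default 10).
#' @param seed integer seed.
#' @return List of class `imputation_result`: `records` (completed data),
#'   `imputed_cells` (data frame id/row, variable), `mode = "covariate_rf"`,
#'   `iterations`, `seed`.
#' @export
impute_covariates_rf <- function(data, covariates, ntree = 100L,
                                 maxiter = 10L, seed = NULL) {
  data <- as.data.frame(data)
  miss <- lapply(covariates, function(v) which(is.na(data[[v]])))
  names(miss) <- covariates
  rates <- vapply(miss, length, 0L) / nrow(data)
  if (any(rates >= 0.5))
    stop("covariate(s) over 50% missing: ",
         paste(covariates[rates >= 0.5], collapse = ", "))
  if (any(rates == 1))
    stop("covariate entirely missing: ",
         paste(covariates[rates == 1], collapse = ", "))
  cells <- do.call(rbind, lapply(covariates, function(v)
    if (length(miss[[v]])) data.frame(row = miss[[v]], variable = v)))
  work <- data
  ## binary/categorical handled as factors for classification forests
  as_model_col <- function(x) {
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 5L) x
    else factor(x)
  }
  for (v in covariates) work[[v]] <- as_model_col(data[[v]])

  if (is.null(cells) || nrow(cells) == 0L) {
    return(structure(list(records = data, imputed_cells = cells,
                          mode = "covariate_rf", iterations = 0L,
                          seed = seed),
                     class = "imputation_result"))
  }

  with_seed(seed, {
    ## initialize with mode / mean
    for (v in covariates) {
      mi <- miss[[v]]
      if (!length(mi)) next
      obs <- work[[v]][-mi]
      fill <- if (is.factor(work[[v]]))
        names(sort(table(obs), decreasing = TRUE))[1L] else mean(obs)
      work[[v]][mi] <- if (is.factor(work[[v]])) factor(fill, levels = levels(work[[v]])) else fill
    }
    order_v <- covariates[order(rates[covariates])]
    active <- order_v[vapply(order_v, function(v) length(miss[[v]]) > 0L, TRUE)]
    prev_crit <- Inf
    prev_work <- work
    it <- 0L
    while (it < maxiter) {
      it <- it + 1L
      for (v in active) {
        mi <- miss[[v]]
        others <- setdiff(covariates, v)
        rf <- randomForest::randomForest(
          x = work[-mi, others, drop = FALSE],
          y = work[[v]][-mi], ntree = ntree)
        pred <- stats::predict(rf, work[mi, others, drop = FALSE])
        work[[v]][mi] <- pred
      }
      crit <- 0
      for (v in active) {
        mi <- miss[[v]]
        new <- work[[v]][mi]; old <- prev_work[[v]][mi]
        crit <- crit + if (is.factor(work[[v]]))
          mean(new != old) else sum((as.numeric(new) - as.numeric(old))^2) /
          max(sum(as.numeric(new)^2), .Machine$double.eps)
      }
      if (crit >= prev_crit) { work <- prev_work; break }
      prev_crit <- crit
      prev_work <- work
    }
    out <- data
    for (v in covariates) {
      mi <- miss[[v]]
      if (!length(mi)) next
      val <- work[[v]][mi]
      out[[v]][mi] <- if (is.factor(work[[v]]) && !is.factor(data[[v]])) {
        if (is.integer(data[[v]])) as.integer(as.character(val))
        else if (is.numeric(data[[v]])) as.numeric(as.character(val))
        else as.character(val)
      } else val
    }
    structure(list(records = out, imputed_cells = cells,
                   mode = "covariate_rf", iterations = it, seed = seed),
              class = "imputation_result")
  })
}

#' Impute missing outcomes
#'
#' Completes missing binary outcomes by one of four schemes:
#' \describe{
#'   \item{`"mixed"` (main analysis)}{fit a mixed-effects logit of the
#'     outcome on the covariates with a community random intercept using
#'     rows with observed outcomes, then draw each missing outcome from a
#'     Bernoulli at the predicted probability, using the community's
#'     empirical-Bayes random-effect mode.}
#'   \item{`"glm"`}{same but a plain logit with no community term, so the
#'     imputed outcomes do not depend on the community structure at all.}
#'   \item{`"best"`}{deterministic best case: missing outcome set to 0
#'     (no risk behavior) for treated participants and 1 for untreated.}
#'   \item{`"worst"`}{the reverse.}
#' }
#' Observed outcomes are never altered.
#'
#' @param network a [risk_network()].
#' @param covariates covariate names for the imputation model (modes
#'   `"mixed"`/`"glm"`); defaults to the network's covariate set.
#' @param structure a [community_structure()] (required for `"mixed"`).
#' @param mode imputation scheme.
#' @param draw_re for `mode = "mixed"`: predict at each community's
#'   empirical-Bayes random-effect mode (default) or, if `TRUE`, draw the
#'   community intercept afresh from \eqn{N(0, \hat\sigma_b^2)}.
#' @param seed integer seed for the Bernoulli draws.
#' @return List of class `imputation_result`: `network` (completed copy),
#'   `imputed_ids`, `audit` (id, field, imputed value, mode, seed), `mode`,
#'   `seed`.
#' @export
impute_outcome <- function(network, covariates = NULL, structure = NULL,
                           mode = c("mixed", "glm", "best", "worst"),
                           draw_re = FALSE, seed = NULL) {
  stopifnot(inherits(network, "risk_network"))
  mode <- match.arg(mode)
  rec <- network$records
  mi <- which(is.na(rec$.outcome))
  if (!length(mi)) {
    return(structure(list(network = network, imputed_ids = character(),
                          audit = data.frame(), mode = mode, seed = seed),
                     class = "imputation_result"))
  }
  if (is.null(covariates)) covariates <- network$covariates
  yimp <- switch(mode,
    best  = ifelse(rec$.treatment[mi] == 1L, 0L, 1L),
    worst = ifelse(rec$.treatment[mi] == 1L, 1L, 0L),
    glm = ,
    mixed = {
      obs <- !is.na(rec$.outcome)
      if (length(unique(rec$.outcome[obs])) < 2L)
        stop("observed outcomes are constant; imputation model unidentifiable")
      dat <- rec
      fml <- stats::reformulate(covariates, response = ".outcome")
      if (mode == "mixed") {
        if (is.null(structure))
          stop("mode = 'mixed' requires a community structure")
        memb <- as_membership(structure, network)[rec$.id]
        fit <- mixed_logit(fml, dat[obs, , drop = FALSE], memb[obs])
        ## empirical-Bayes modes from observed rows of each community
        eta_obs <- drop(fit$X %*% fit$theta)
        comm_levels <- levels(factor(memb[obs]))
        b <- if (fit$sigma == 0) rep(0, length(comm_levels))
        else if (draw_re)
          with_seed(if (is.null(seed)) NULL else seed + 1L,
                    stats::rnorm(length(comm_levels), 0, fit$sigma))
        else re_modes(fit$y, eta_obs, fit$comm, fit$sigma)$mode
        names(b) <- comm_levels
        mf <- stats::model.frame(stats::delete.response(fit$terms),
                                 dat[mi, , drop = FALSE],
                                 na.action = stats::na.fail,
                                 xlev = fit$xlevels)
        Xm <- stats::model.matrix(stats::delete.response(fit$terms), mf)
        bmi <- b[as.character(memb[mi])]
        bmi[is.na(bmi)] <- 0  # community with no observed outcomes
        p <- expit(drop(Xm %*% fit$theta) + bmi)
      } else {
        fit <- stats::glm(fml, data = dat[obs, , drop = FALSE],
                          family = stats::binomial())
        p <- stats::predict(fit, newdata = dat[mi, , drop = FALSE],
                            type = "response")
      }
      with_seed(seed, stats::rbinom(length(mi), 1L, p))
    })
  out <- network
  out$records$.outcome[mi] <- yimp
  ## keep the user-facing outcome column in step when present
  audit <- data.frame(id = rec$.id[mi], field = "outcome",
                      original = NA, imputed = yimp, mode = mode,
                      seed = if (is.null(seed)) NA_integer_ else seed,
                      stringsAsFactors = FALSE)
  structure(list(network = out, imputed_ids = rec$.id[mi], audit = audit,
                 mode = mode, seed = seed),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("Imputation (", x$mode, "): ", sep = "")
  if (!is.null(x$audit) && nrow(x$audit)) cat(nrow(x$audit), "outcomes imputed\n")
  else if (!is.null(x$imputed_cells) && NROW(x$imputed_cells))
    cat(nrow(x$imputed_cells), "covariate cells imputed in",
        x$iterations, "sweep(s)\n")
  else cat("nothing to impute\n")
  invisible(x)
}
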
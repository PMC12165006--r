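#' Read a flat key = value run configuration
#'
#' Parses a plain-text configuration of `key = value` lines (`#` comments
#' allowed). Comma-separated values become vectors; `alpha_pairs` uses
#' `a:b` pairs separated by commas, e.g. `0.6:0.2,0.4:0.2`.
#'
#' Recognized keys: `edge_file`, `attr_file`, `delim`, `id`, `treatment`,
#' `outcome`, `covariates` (candidate list), `methods` (`cfg,le`),
#' `alphas`, `alpha_pairs`, `imputation` (`mixed`, `glm`, `best`, `worst`),
#' `trim_low`, `trim_high`, `gamma_max`, `gamma_step`, `perturb_reps`,
#' `reference_p` (node-reassignment proportions), `seed`.
#'
#' @param path file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  if (!is.null(out$alpha_pairs)) {
    pr <- strsplit(as.character(out$alpha_pairs), ":", fixed = TRUE)
    out$alpha_pairs <- do.call(rbind, lapply(pr, as.numeric))
  }
  out
}

#' Run the full spillover analysis pipeline
#'
#' Executes, per detection method: covariate imputation (random forest) if
#' any covariate cell is missing, community detection, outcome imputation
#' (mode-dependent; the `"mixed"` main analysis uses that method's
#' communities for the random effect, so imputations can differ slightly
#' between methods, while `"glm"` removes this difference), covariate
#' screening, propensity fitting, IPW effect estimation with an
#' extreme-weight-trimmed variant, and the perturbation significance
#' analysis. Writes delimited result tables (with a `#`-comment metadata
#' header recording the seed) into `out_dir` and returns the full results
#' invisibly.
#'
#' All child seeds are derived deterministically from `config$seed`
#' (stage-indexed offsets), so a rerun with the same configuration is
#' byte-identical.
#'
#' @param config a named list (see [read_run_config()]) or a path to a
#'   config file. Instead of `edge_file`/`attr_file`, a ready
#'   [risk_network()] may be supplied as `config$network`.
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @return Invisibly, a list with one element per method: `structure`,
#'   `screening`, `effects` (a [spillover_ipw()]), `trimmed`, `curves`
#'   (observed and null [perturbation_curve()]s), `references`,
#'   `imputation` audit.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  cfg <- config
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  methods <- if (is.null(cfg$methods)) c("cfg", "le") else
    match.arg(as.character(cfg$methods), c("cfg", "le"), several.ok = TRUE)
  alphas <- if (is.null(cfg$alphas)) c(0.2, 0.4, 0.6) else cfg$alphas
  pairs <- if (is.null(cfg$alpha_pairs)) default_pairs() else
    validate_pairs(cfg$alpha_pairs)
  imputation <- if (is.null(cfg$imputation)) "mixed" else
    match.arg(cfg$imputation, c("mixed", "glm", "best", "worst"))
  trim_low <- if (is.null(cfg$trim_low)) 0.001 else cfg$trim_low
  trim_high <- if (is.null(cfg$trim_high)) Inf else cfg$trim_high
  gammas <- seq(0, if (is.null(cfg$gamma_max)) 1 else cfg$gamma_max,
                by = if (is.null(cfg$gamma_step)) 0.02 else cfg$gamma_step)
  reps <- if (is.null(cfg$perturb_reps)) 30L else as.integer(cfg$perturb_reps)
  ref_p <- if (is.null(cfg$reference_p)) c(0.10, 0.20) else cfg$reference_p

  net <- if (!is.null(cfg$network)) cfg$network else
    read_risk_network(cfg$edge_file, cfg$attr_file,
                      delim = if (is.null(cfg$delim)) "," else cfg$delim,
                      id = if (is.null(cfg$id)) "id" else cfg$id,
                      treatment = if (is.null(cfg$treatment)) "treatment"
                      else cfg$treatment,
                      outcome = if (is.null(cfg$outcome)) "outcome"
                      else cfg$outcome)
  candidates <- if (is.null(cfg$covariates)) net$covariates else cfg$covariates

  ## stage 1: covariate imputation (shared across methods)
  cov_imp <- NULL
  if (anyNA(net$records[candidates])) {
    cov_imp <- impute_covariates_rf(net$records, candidates,
                                    seed = child_seed(seed, 1L))
    net$records <- cov_imp$records
  }

  results <- list()
  for (mi in seq_along(methods)) {
    method <- methods[mi]
    stage <- function(label, expr) {
      tryCatch(expr, error = function(e)
        stop("pipeline stage '", label, "' (", method, "): ",
             conditionMessage(e), call. = FALSE))
    }
    structure_m <- stage("detect", detect_communities(net, method))
    out_imp <- stage("impute_outcome",
      impute_outcome(net, covariates = candidates, structure = structure_m,
                     mode = imputation,
                     seed = child_seed(seed, 10L + mi)))
    net_m <- out_imp$network
    memb <- structure_m$assignment[net_m$records$.id]
    scr <- stage("screen",
      screen_covariates(net_m$records, ".treatment", candidates, memb))
    fml <- stats::reformulate(scr$selected)
    eff <- stage("estimate",
      spillover_ipw(net_m, structure_m, fml, alphas = alphas, pairs = pairs))
    trm <- stage("trim", trim_extreme(eff, low = trim_low, high = trim_high))
    curve_obs <- stage("perturbation",
      perturbation_curve(net, method, gammas = gammas, reps = reps,
                         network_tag = "observed",
                         seed = child_seed(seed, 100L + mi)))
    nullnet <- stage("null_network",
      null_network(net, seed = child_seed(seed, 200L + mi)))
    curve_null <- stage("perturbation_null",
      perturbation_curve(nullnet, method, gammas = gammas, reps = reps,
                         network_tag = "null",
                         seed = child_seed(seed, 300L + mi)))
    refs <- vapply(ref_p, function(p)
      reassignment_reference(structure_m, p, reps = 500L,
                             seed = child_seed(seed, 400L + mi)), 0)
    names(refs) <- paste0("p", ref_p)
    results[[method]] <- list(structure = structure_m,
                              screening = scr,
                              imputation = out_imp$audit,
                              effects = eff, trimmed = trm,
                              curves = list(observed = curve_obs,
                                            null = curve_null),
                              references = refs)
  }
  results$covariate_imputation <- cov_imp
  results$seed <- seed

  if (!is.null(out_dir)) write_pipeline_outputs(results, methods, out_dir)
  invisible(results)
}

write_pipeline_outputs <- function(results, methods, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# netspill %s | seed=%s | R %s",
                 as.character(utils::packageVersion("netspill")),
                 results$seed, getRversion())
  wr <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
  }
  for (method in methods) {
    r <- results[[method]]
    wr(r$effects$estimates, paste0("effects_", method, ".csv"))
    wr(r$trimmed$estimates, paste0("effects_trimmed_", method, ".csv"))
    wr(r$effects$weights, paste0("weights_", method, ".csv"))
    wr(rbind(r$curves$observed$summary, r$curves$null$summary),
       paste0("perturbation_", method, ".csv"))
    wr(data.frame(reference = names(r$references), voi = r$references),
       paste0("references_", method, ".csv"))
    wr(data.frame(id = names(r$structure$assignment),
                  community = r$structure$assignment),
       paste0("communities_", method, ".csv"))
    if (nrow(r$imputation))
      wr(r$imputation, paste0("imputation_audit_", method, ".csv"))
  }
  invisible(NULL)
}
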
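## Numerically safe helpers shared across modules.

expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p) - log1p(-p)

## log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Bernoulli log-likelihood terms log(h^a (1-h)^(1-a)) from the linear
## predictor eta; stable for large |eta|.
bernoulli_loglik <- function(a, eta) {
  ## log expit(eta) = -log1p(exp(-eta)); log(1-expit(eta)) = -log1p(exp(eta))
  ifelse(a == 1, -log1p(exp(-eta)), -log1p(exp(eta)))
}

## Relabel an assignment vector (any labels) to contiguous integers 1..N in
## order of first appearance, preserving names.
relabel_contiguous <- function(assignment) {
  labs <- unique(assignment)
  out <- match(assignment, labs)
  names(out) <- names(assignment)
  out
}

## Deterministic child seeds derived from a master seed; offsets keep each
## pipeline stage independently reproducible. Kept below 2^31 - 1.
child_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1009 + offset * 9973) %% 2147483647L)
}

## Run expr under a locally set seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Two partitions of the same node set, equal up to label permutation?
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  ta <- as.integer(factor(a, levels = unique(a)))
  tb <- as.integer(factor(b, levels = unique(b)))
  all(ta == tb)
}
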
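#' Community structure objects
#'
#' A `community_structure` is a partition of the network's nodes into
#' communities (the interference sets of the analysis): an assignment vector
#' named by participant id with contiguous integer labels `1..N`, together
#' with the community sizes, the detection method tag, and the modularity of
#' the partition on its source graph.
#'
#' @param assignment vector of community labels named by node id (any label
#'   type; relabelled to contiguous integers in order of first appearance).
#' @param method tag: `"cfg"`, `"le"` or `"given"`.
#' @param network optional [risk_network()] or `igraph` graph on which to
#'   compute the partition's modularity.
#' @return An object of class `community_structure` with elements
#'   `assignment`, `sizes`, `N`, `method`, `modularity`.
#' @export
community_structure <- function(assignment, method = "given", network = NULL) {
  assignment <- relabel_contiguous(assignment)
  sizes <- as.integer(table(assignment))
  q <- if (!is.null(network)) modularity_score(network, assignment) else NA_real_
  structure(list(assignment = assignment, sizes = sizes,
                 N = length(sizes), method = method, modularity = q),
            class = "community_structure")
}

#' @export
print.community_structure <- function(x, ...) {
  cat("Community structure (", x$method, "): ", x$N, " communities, sizes ",
      min(x$sizes), "-", max(x$sizes), sep = "")
  if (!is.na(x$modularity)) cat(", Q = ", format(x$modularity, digits = 4), sep = "")
  cat("\n")
  invisible(x)
}

## Accept a risk_network or a bare igraph graph.
as_graph <- function(x) {
  if (inherits(x, "risk_network")) return(x$graph)
  if (igraph::is_igraph(x)) return(x)
  stop("expected a risk_network or an igraph graph")
}

#' Modularity of a partition
#'
#' Computes Newman-Girvan modularity
#' \eqn{Q = \sum_c [e_c/m - (d_c/2m)^2]}, the difference between the observed
#' and the randomly expected proportion of edges falling within communities,
#' where \eqn{e_c} is the number of edges inside community \eqn{c},
#' \eqn{d_c} its total degree and \eqn{m} the number of edges.
#'
#' @param network a [risk_network()] or `igraph` graph with at least one edge.
#' @param structure a [community_structure()] or assignment vector (named by
#'   node id, or unnamed in vertex order).
#' @return Modularity score in \[-1, 1\].
#' @export
modularity_score <- function(network, structure) {
  g <- as_graph(network)
  m <- igraph::ecount(g)
  if (m < 1L) stop("modularity undefined on an empty edge set")
  memb <- if (inherits(structure, "community_structure"))
    structure$assignment else structure
  vn <- igraph::V(g)$name
  if (!is.null(names(memb))) {
    absent <- setdiff(vn, names(memb))
    if (length(absent))
      stop("node(s) absent from the partition: ",
           paste(absent, collapse = ", "))
    memb <- memb[vn]
  } else if (length(memb) != igraph::vcount(g)) {
    stop("unnamed assignment must have one entry per node")
  }
  memb <- as.integer(factor(memb))
  k <- max(memb)
  e <- igraph::as_edgelist(g, names = FALSE)
  within <- memb[e[, 1L]] == memb[e[, 2L]]
  ec <- tabulate(memb[e[, 1L]][within], nbins = k)
  dc <- vapply(seq_len(k), function(c) sum(igraph::degree(g)[memb == c]), 0)
  sum(ec / m - (dc / (2 * m))^2)
}

#' Detect communities by modularity maximization
#'
#' Runs one of the two modularity-maximizing detectors used to define the
#' interference sets: greedy agglomeration (`"cfg"`; start from singletons and
#' repeatedly merge the pair of communities giving the largest modularity
#' increase, until no merge increases modularity) or leading-eigenvector
#' recursive bisection (`"le"`; split by the sign pattern of the leading
#' eigenvector of the generalized modularity matrix, accepting a split only
#' when it strictly increases modularity).
#'
#' Detection runs independently on each connected component (with the
#' component's own edge count as \eqn{m}); community labels are then unified
#' globally. Both detectors are deterministic: greedy merge ties (within
#' 1e-12 of the best gain) are broken by the lexicographically smallest pair
#' of community labels, and eigenvector sign is fixed by convention.
#'
#' @param network a [risk_network()] or `igraph` graph; simple, undirected,
#'   with no degree-0 nodes and at least one edge.
#' @param method `"cfg"` (greedy agglomerative) or `"le"`
#'   (leading eigenvector).
#' @return A [community_structure()] with `modularity` computed on the input
#'   graph.
#' @examples
#' g <- igraph::make_graph(~ a - b, a - c, b - c, d - e, d - f, e - f, c - d)
#' detect_communities(g, "cfg")  # the two triangles, Q = 5/14
#' @export
detect_communities <- function(network, method = c("cfg", "le")) {
  method <- match.arg(method)
  g <- as_graph(network)
  if (igraph::any_multiple(g) || any(igraph::which_loop(g)))
    stop("graph must be simple (no duplicate edges or self-loops)")
  if (igraph::ecount(g) < 1L) stop("detection requires at least one edge")
  ## isolated nodes (possible in perturbed copies) become singleton
  ## communities via their size-1 components
  comp <- igraph::components(g)
  vn <- igraph::V(g)$name
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(g)))
  assignment <- integer(igraph::vcount(g))
  next_label <- 0L
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    adj <- igraph::as_adjacency_matrix(
      igraph::induced_subgraph(g, idx), sparse = FALSE)
    labs <- if (length(idx) == 1L) 1L
            else if (method == "cfg") cfg_component(adj)
            else le_component(adj)
    labs <- relabel_contiguous(labs)
    assignment[idx] <- labs + next_label
    next_label <- next_label + max(labs)
  }
  names(assignment) <- vn
  community_structure(assignment, method = method, network = g)
}

## Greedy agglomerative modularity maximization on one component.
## adj: dense 0/1 adjacency matrix. Returns integer labels.
cfg_component <- function(adj, tol = 1e-12) {
  n <- nrow(adj)
  m <- sum(adj) / 2
  E <- adj                   # E[a,b]: edges between communities a and b
  d <- rowSums(adj)          # community total degrees
  active <- rep(TRUE, n)
  merges <- matrix(0L, n, 2L)
  ## agglomerate all the way (only edge-joined pairs; a cross-component merge
  ## can never raise Q), tracking cumulative Q to return the best step
  cumq <- numeric(n)
  q <- -sum((d / (2 * m))^2)  # modularity of the singleton partition
  cumq[1L] <- q
  steps <- 0L
  repeat {
    act <- which(active)
    if (length(act) < 2L) break
    Ea <- E[act, act, drop = FALSE]
    dq <- Ea / m - outer(d[act], d[act]) / (2 * m^2)
    dq[Ea == 0] <- -Inf      # only communities joined by an edge can merge
    diag(dq) <- -Inf
    best <- max(dq)
    if (!is.finite(best)) break
    cand <- which(dq >= best - tol, arr.ind = TRUE)
    pair <- cbind(pmin(cand[, 1L], cand[, 2L]), pmax(cand[, 1L], cand[, 2L]))
    ord <- order(pair[, 1L], pair[, 2L])
    a <- act[pair[ord[1L], 1L]]
    b <- act[pair[ord[1L], 2L]]
    exact_dq <- E[a, b] / m - d[a] * d[b] / (2 * m^2)
    ## merge b into a (a < b)
    E[a, ] <- E[a, ] + E[b, ]
    E[, a] <- E[, a] + E[, b]
    d[a] <- d[a] + d[b]
    active[b] <- FALSE
    steps <- steps + 1L
    merges[steps, ] <- c(a, b)
    q <- q + exact_dq
    cumq[steps + 1L] <- q
  }
  ## earliest step attaining the maximum (within tolerance), for determinism
  qmax <- max(cumq[seq_len(steps + 1L)])
  kbest <- which(cumq[seq_len(steps + 1L)] >= qmax - tol)[1L] - 1L
  lab <- seq_len(n)
  for (k in seq_len(kbest)) lab[lab == merges[k, 2L]] <- merges[k, 1L]
  lab
}

## Leading-eigenvector recursive bisection on one component.
## adj: dense adjacency. Returns integer labels.
le_component <- function(adj, eig_tol = 1e-10, dq_tol = 1e-12,
                         dense_limit = 256L) {
  n <- nrow(adj)
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  lab <- rep(1L, n)
  queue <- list(seq_len(n))
  next_lab <- 1L
  while (length(queue)) {
    grp <- queue[[1L]]
    queue <- queue[-1L]
    if (length(grp) < 2L) next
    B <- adj[grp, grp, drop = FALSE] - outer(deg[grp], deg[grp]) / (2 * m)
    Bg <- B
    diag(Bg) <- diag(Bg) - rowSums(B)
    ev <- leading_eigen(Bg, dense_limit = dense_limit)
    if (ev$value <= eig_tol) next  # indivisible
    v <- ev$vector
    pivot <- which(abs(v) > 1e-12)[1L]
    if (is.na(pivot)) next
    if (v[pivot] < 0) v <- -v
    s <- ifelse(v >= 0, 1, -1)
    if (all(s == s[1L])) next
    dq <- drop(s %*% Bg %*% s) / (4 * m)
    if (dq <= dq_tol) next
    g1 <- grp[s > 0]
    g2 <- grp[s < 0]
    next_lab <- next_lab + 1L
    lab[g2] <- next_lab
    queue <- c(queue, list(g1), list(g2))
  }
  lab
}

## Leading (largest) eigenpair of a symmetric matrix. Dense decomposition for
## small matrices; shifted power iteration above dense_limit.
leading_eigen <- function(S, dense_limit = 256L, tol = 1e-10, maxit = 10000L) {
  n <- nrow(S)
  if (n <= dense_limit) {
    e <- eigen(S, symmetric = TRUE)
    return(list(value = e$values[1L], vector = e$vectors[, 1L]))
  }
  shift <- max(rowSums(abs(S)))  # Gershgorin bound makes S + shift*I PSD
  ## generic deterministic start; the constant vector is an exact null
  ## eigenvector of the generalized modularity matrix and must be avoided
  v <- sin(seq_len(n))
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (it in seq_len(maxit)) {
    w <- drop(S %*% v) + shift * v
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    lam_new <- drop(w %*% (S %*% w))
    if (abs(lam_new - lam) < tol) {
      return(list(value = lam_new, vector = w))
    }
    lam <- lam_new
    v <- w
  }
  stop("eigen-solver failed to converge on a subgraph of size ", n)
}
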
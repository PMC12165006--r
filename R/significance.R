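#' Normalized variation of information between two partitions
#'
#' The variation of information between community structures \eqn{C} and
#' \eqn{C'} on the same node set is \eqn{H(C|C') + H(C'|C)}, the information
#' needed to describe each partition given the other, computed from the
#' joint contingency of the two assignments. It is normalized by
#' \eqn{\log n} to the 0-1 scale (natural logarithms throughout; the base
#' cancels in the ratio). The normalized VOI is a metric on partitions of a
#' fixed node set: 0 iff the partitions coincide, 1 exactly for the
#' all-singletons versus one-block contrast.
#'
#' @param c1,c2 [community_structure()] objects or assignment vectors named
#'   by node id, covering the identical node set of size at least 2.
#' @return Normalized VOI in \[0, 1\].
#' @export
voi <- function(c1, c2) {
  a1 <- if (inherits(c1, "community_structure")) c1$assignment else c1
  a2 <- if (inherits(c2, "community_structure")) c2$assignment else c2
  if (is.null(names(a1)) || is.null(names(a2))) {
    if (length(a1) != length(a2))
      stop("unnamed assignments must have equal length")
  } else {
    if (!setequal(names(a1), names(a2)))
      stop("partitions cover different node sets")
    a2 <- a2[names(a1)]
  }
  n <- length(a1)
  if (n < 2L) stop("need at least 2 nodes")
  joint <- table(a1, a2) / n
  pk <- rowSums(joint)
  pl <- colSums(joint)
  nz <- joint > 0
  h_joint <- -sum(joint[nz] * log(joint[nz]))
  h1 <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  h2 <- -sum(pl[pl > 0] * log(pl[pl > 0]))
  v <- (h_joint - h1) + (h_joint - h2)  # H(C2|C1) + H(C1|C2)
  min(max(v / log(n), 0), 1)
}

#' Perturb a network by randomly reassigning edges
#'
#' Deletes \eqn{\lceil \gamma |E| \rceil} edges chosen uniformly without
#' replacement and replaces each with a currently absent pair (no
#' self-loops, no duplicates), preserving both the node set and the edge
#' count. With `mode = "uniform"` (default) replacement pairs are drawn
#' uniformly from all non-edges; `mode = "degree"` draws endpoints with
#' probability proportional to the original degrees (configuration-model
#' style replacement).
#'
#' @param network a [risk_network()] or `igraph` graph.
#' @param gamma proportion of edges to reassign, in \[0, 1\].
#' @param mode replacement law, `"uniform"` or `"degree"`.
#' @param seed integer seed.
#' @return Same type as the input, with the perturbed edge set.
#' @export
perturb_network <- function(network, gamma, mode = c("uniform", "degree"),
                            seed = NULL) {
  stopifnot(gamma >= 0, gamma <= 1)
  mode <- match.arg(mode)
  g <- as_graph(network)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  nrew <- ceiling(gamma * m)
  if (nrew == 0L) return(network)
  if (choose(n, 2) - m < nrew)
    stop("graph too dense to place replacement edges")
  with_seed(seed, {
    el <- igraph::as_edgelist(g, names = FALSE)
    key <- function(i, j) pmin(i, j) * (n + 1) + pmax(i, j)
    ## replacements must avoid the original edge set (so exactly nrew edges
    ## differ) as well as each other
    present <- new.env(parent = emptyenv(), size = m)
    for (r in seq_len(m)) assign(as.character(key(el[r, 1L], el[r, 2L])), TRUE,
                                 envir = present)
    drop_idx <- sample.int(m, nrew)
    deg <- igraph::degree(g)
    new_edges <- matrix(0L, nrew, 2L)
    for (r in seq_len(nrew)) {
      for (try in seq_len(20000L)) {
        if (mode == "uniform") {
          i <- sample.int(n, 1L); j <- sample.int(n, 1L)
        } else {
          i <- sample.int(n, 1L, prob = deg)
          j <- sample.int(n, 1L, prob = deg)
        }
        if (i == j) next
        k <- as.character(key(i, j))
        if (!is.null(present[[k]])) next
        assign(k, TRUE, envir = present)
        new_edges[r, ] <- c(i, j)
        break
      }
      if (new_edges[r, 1L] == 0L)
        stop("could not place a replacement edge (graph too dense)")
    }
    el2 <- rbind(el[-drop_idx, , drop = FALSE], new_edges)
    g2 <- igraph::make_empty_graph(n, directed = FALSE)
    g2 <- igraph::add_edges(g2, t(el2))
    igraph::V(g2)$name <- igraph::V(g)$name
    replace_graph(network, g2)
  })
}

## Swap the graph inside a risk_network (or pass an igraph straight through).
replace_graph <- function(network, g2) {
  if (inherits(network, "risk_network")) {
    network$graph <- g2
    network
  } else g2
}

#' Degree-matched null network
#'
#' Randomizes the edges of the network while preserving the exact degree
#' sequence, via repeated double-edge swaps (attempted `swaps_per_edge` times
#' per edge; swaps that would create a self-loop or duplicate edge are
#' skipped). The result has the same distribution of edges per participant
#' but no community structure, serving as the reference ("null") network in
#' the perturbation analysis.
#'
#' @param network a [risk_network()] or `igraph` graph.
#' @param swaps_per_edge attempted swaps per edge (default 100).
#' @param seed integer seed.
#' @return Same type as the input.
#' @export
null_network <- function(network, swaps_per_edge = 100L, seed = NULL) {
  g <- as_graph(network)
  with_seed(seed, {
    g2 <- igraph::rewire(g, igraph::keeping_degseq(
      niter = swaps_per_edge * igraph::ecount(g)))
    replace_graph(network, g2)
  })
}

#' Perturbation curve of community-structure robustness
#'
#' For each edge-reassignment proportion \eqn{\gamma} in `gammas`, detects
#' the community structure of the base network once, perturbs the network
#' `reps` times, re-detects on every perturbed copy, and computes the
#' normalized variation of information against the base structure. The
#' mean/min/max of the `reps` values trace how quickly the detected
#' structure degrades: a significant community structure resists small
#' perturbations (low VOI at small \eqn{\gamma}), while a null network's
#' curve rises immediately.
#'
#' @param network a [risk_network()] or `igraph` graph.
#' @param method detection method passed to [detect_communities()].
#' @param gammas grid of proportions (default 0 to 1 in steps of 0.02).
#' @param reps perturbed copies per gamma (default 30).
#' @param mode edge-replacement law, see [perturb_network()].
#' @param network_tag label stored with the curve (`"observed"` or
#'   `"null"`).
#' @param seed integer seed; per-replicate seeds are derived from it.
#' @return Object of class `perturbation_curve`: `summary` (data frame
#'   gamma, mean, min, max, network_tag), `samples` (length(gammas) x reps
#'   matrix), `base_structure`, `method`, `seed`.
#' @export
perturbation_curve <- function(network, method = c("cfg", "le"),
                               gammas = seq(0, 1, by = 0.02), reps = 30L,
                               mode = c("uniform", "degree"),
                               network_tag = "observed", seed = NULL) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  base <- detect_communities(network, method)
  samples <- matrix(NA_real_, length(gammas), reps)
  for (gi in seq_along(gammas)) {
    for (r in seq_len(reps)) {
      s <- if (is.null(seed)) NULL else
        child_seed(seed, gi * 1000L + r)
      pert <- perturb_network(network, gammas[gi], mode = mode, seed = s)
      cs <- detect_communities(pert, method)
      samples[gi, r] <- voi(base, cs)
    }
  }
  summ <- data.frame(gamma = gammas,
                     mean = rowMeans(samples),
                     min = apply(samples, 1L, min),
                     max = apply(samples, 1L, max),
                     network_tag = network_tag,
                     stringsAsFactors = FALSE)
  structure(list(summary = summ, samples = samples, base_structure = base,
                 method = method, mode = mode, network_tag = network_tag,
                 seed = seed),
            class = "perturbation_curve")
}

#' @export
print.perturbation_curve <- function(x, ...) {
  cat("Perturbation curve (", x$method, ", ", x$network_tag, "): ",
      nrow(x$summary), " gamma points x ", ncol(x$samples),
      " replicates\n", sep = "")
  print(utils::head(x$summary, 5))
  invisible(x)
}

#' @export
plot.perturbation_curve <- function(x, references = NULL, col = "grey40", ...) {
  s <- x$summary
  graphics::plot(s$gamma, s$mean, type = "n", ylim = c(0, 1),
                 xlab = expression(gamma), ylab = "normalized VOI", ...)
  graphics::polygon(c(s$gamma, rev(s$gamma)), c(s$min, rev(s$max)),
                    col = grDevices::adjustcolor(col, 0.3), border = NA)
  graphics::lines(s$gamma, s$mean, col = col, lwd = 2)
  if (!is.null(references))
    graphics::abline(h = references, lty = 2)
  invisible(x)
}

#' Node-reassignment reference level
#'
#' The VOI level that corresponds to moving a proportion `p` of nodes to
#' other communities: averages, over `reps` replicates, the normalized VOI
#' between the structure and a copy in which \eqn{\lceil p n \rceil}
#' uniformly chosen nodes are each moved to a uniformly chosen different
#' existing community. Drawn as a horizontal reference line against
#' perturbation curves: the \eqn{\gamma} at which the mean curve crosses the
#' level is the proportion of edge reassignment that scrambles that share of
#' the nodes.
#'
#' @param structure a [community_structure()] with at least 2 communities.
#' @param p proportion of nodes to reassign, in (0, 1).
#' @param reps replicates (default 500).
#' @param seed integer seed.
#' @return Mean normalized VOI (scalar).
#' @export
reassignment_reference <- function(structure, p, reps = 500L, seed = NULL) {
  stopifnot(inherits(structure, "community_structure"), p > 0, p < 1)
  if (structure$N < 2L)
    stop("need at least 2 communities to reassign nodes")
  a <- structure$assignment
  n <- length(a)
  k <- ceiling(p * n)
  labs <- seq_len(structure$N)
  with_seed(seed, {
    mean(vapply(seq_len(reps), function(r) {
      a2 <- a
      idx <- sample.int(n, k)
      for (v in idx) {
        others <- labs[labs != a2[[v]]]
        a2[[v]] <- others[sample.int(length(others), 1L)]
      }
      voi(a, a2)
    }, 0))
  })
}

#' Crossing point of a perturbation curve with a reference level
#'
#' Smallest \eqn{\gamma} at which the curve's mean VOI reaches the given
#' level, interpolated linearly between adjacent grid points.
#'
#' @param curve a [perturbation_curve()].
#' @param level reference VOI level.
#' @return The crossing \eqn{\gamma}, or `NA` if the curve never reaches the
#'   level.
#' @export
crossing_gamma <- function(curve, level) {
  stopifnot(inherits(curve, "perturbation_curve"))
  s <- curve$summary
  above <- which(s$mean >= level)
  if (!length(above)) return(NA_real_)
  i <- above[1L]
  if (i == 1L) return(s$gamma[1L])
  g0 <- s$gamma[i - 1L]; g1 <- s$gamma[i]
  v0 <- s$mean[i - 1L]; v1 <- s$mean[i]
  if (v1 == v0) return(g1)
  g0 + (level - v0) / (v1 - v0) * (g1 - g0)
}
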
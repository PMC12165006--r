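#' Build a participant risk network
#'
#' Constructs a simple undirected network of study participants together with
#' their attribute records. Edge direction in the input is ignored; duplicate
#' edges are collapsed; self-loops are rejected. Optionally removes isolated
#' participants (degree 0), mirroring the usual pre-analysis cleaning of
#' sociometric risk-network data.
#'
#' @param edges two-column matrix or data frame of participant id pairs
#'   (character or coercible to character).
#' @param attributes data frame of participant records, one row per id.
#' @param id,treatment,outcome names of the id, binary treatment and binary
#'   outcome columns in `attributes`. The outcome may contain `NA`; the
#'   treatment may not.
#' @param covariates character vector of covariate column names to carry; by
#'   default every remaining column.
#' @param drop_isolates drop participants with no edges? Default `TRUE`.
#' @param yes,no accepted encodings of 1 and 0 for treatment/outcome, in
#'   addition to numeric 0/1. Anything else is an error: silent coercion
#'   hides coding bugs.
#'
#' @return An object of class `risk_network`: a list with an `igraph` graph
#'   (`$graph`, vertices named by participant id), the aligned attribute
#'   records (`$records`), and counts of collapsed duplicates and removed
#'   isolates (`$n_duplicate_edges`, `$n_isolates_removed`).
#' @examples
#' edges <- data.frame(from = c("a", "b", "b"), to = c("b", "a", "c"))
#' attrs <- data.frame(id = c("a", "b", "c", "d"),
#'                     treatment = c(1, 0, 1, 0),
#'                     outcome = c(1, 0, NA, 1))
#' net <- risk_network(edges, attrs)
#' net$n_isolates_removed  # d had no edges
#' @export
risk_network <- function(edges, attributes, id = "id", treatment = "treatment",
                         outcome = "outcome", covariates = NULL,
                         drop_isolates = TRUE,
                         yes = c("1", "yes", "Yes"), no = c("0", "no", "No")) {
  stopifnot(is.data.frame(attributes))
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) stop("edge input must have two id columns")
  for (col in c(id, treatment, outcome)) {
    if (!col %in% names(attributes))
      stop("attribute column not found: ", col)
  }
  ids <- as.character(attributes[[id]])
  if (anyDuplicated(ids))
    stop("duplicate participant record(s) for id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         " (merge duplicate enrollments upstream)")

  code_binary <- function(x, what, allow_na) {
    x <- as.character(x)
    out <- rep(NA_integer_, length(x))
    out[x %in% yes] <- 1L
    out[x %in% no] <- 0L
    bad <- !is.na(x) & is.na(out)
    if (any(bad))
      stop("uncodable ", what, " value(s): ",
           paste(unique(x[bad]), collapse = ", "))
    if (!allow_na && anyNA(out))
      stop(what, " must be fully observed (missing for id(s): ",
           paste(ids[is.na(out)], collapse = ", "), ")")
    out
  }

  e1 <- as.character(edges[[1L]])
  e2 <- as.character(edges[[2L]])
  unknown <- setdiff(c(e1, e2), ids)
  if (length(unknown))
    stop("edge endpoint(s) not present in attribute table: ",
         paste(unknown, collapse = ", "))
  if (any(e1 == e2))
    stop("self-loop edge(s) for id(s): ",
         paste(unique(e1[e1 == e2]), collapse = ", "))
  ## canonical unordered pairs: lexicographically sorted endpoints
  a <- pmin(e1, e2)
  b <- pmax(e1, e2)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  a <- a[!dup]; b <- b[!dup]

  records <- attributes
  records$.id <- ids
  records$.treatment <- code_binary(attributes[[treatment]], "treatment",
                                    allow_na = FALSE)
  records$.outcome <- code_binary(attributes[[outcome]], "outcome",
                                  allow_na = TRUE)
  if (is.null(covariates))
    covariates <- setdiff(names(attributes), c(id, treatment, outcome))
  missing_cov <- setdiff(covariates, names(attributes))
  if (length(missing_cov))
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))

  keep <- sort(ids)
  n_isolates <- 0L
  if (drop_isolates) {
    connected <- unique(c(a, b))
    n_isolates <- sum(!keep %in% connected)
    keep <- keep[keep %in% connected]
  }
  records <- records[match(keep, records$.id), , drop = FALSE]
  rownames(records) <- NULL

  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = keep, stringsAsFactors = FALSE))

  structure(list(graph = g,
                 records = records,
                 covariates = covariates,
                 n_duplicate_edges = n_dup,
                 n_isolates_removed = n_isolates),
            class = "risk_network")
}

#' Read a risk network from delimited files
#'
#' @param edge_file path to a two-column delimited edge list (header optional;
#'   autodetected by checking whether the first row's ids occur in the
#'   attribute table).
#' @param attr_file path to a delimited attribute table with header.
#' @param delim field delimiter, default comma.
#' @param ... passed to [risk_network()] (column roles, coding, isolates).
#' @return A [risk_network()] object.
#' @export
read_risk_network <- function(edge_file, attr_file, delim = ",", ...) {
  attrs <- utils::read.table(attr_file, sep = delim, header = TRUE,
                             stringsAsFactors = FALSE, comment.char = "#")
  edges <- utils::read.table(edge_file, sep = delim, header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
  dots <- list(...)
  idcol <- if (!is.null(dots$id)) dots$id else "id"
  ids <- as.character(attrs[[idcol]])
  if (nrow(edges) && !all(as.character(unlist(edges[1L, 1:2])) %in% ids))
    edges <- edges[-1L, , drop = FALSE]  # header row
  risk_network(edges, attrs, ...)
}

#' @export
print.risk_network <- function(x, ...) {
  cat("Risk network:", network_size(x), "participants,",
      igraph::ecount(x$graph), "edges\n")
  cat("  treated:", sum(x$records$.treatment),
      sprintf("(%.0f%%)", 100 * mean(x$records$.treatment)), "\n")
  ymiss <- sum(is.na(x$records$.outcome))
  cat("  outcome missing:", ymiss,
      sprintf("(%.0f%%)", 100 * ymiss / network_size(x)), "\n")
  if (x$n_duplicate_edges || x$n_isolates_removed)
    cat("  cleaned:", x$n_duplicate_edges, "duplicate edges collapsed,",
        x$n_isolates_removed, "isolates removed\n")
  invisible(x)
}

#' Number of participants and their ids
#' @param network a [risk_network()].
#' @return `network_size()` the participant count; `network_ids()` the
#'   participant ids in canonical (sorted) order.
#' @export
network_size <- function(network) igraph::vcount(network$graph)

#' @rdname network_size
#' @export
network_ids <- function(network) igraph::V(network$graph)$name

## Edge list as a 2-column character matrix (canonical order).
network_edges <- function(network) {
  e <- igraph::as_edgelist(network$graph, names = TRUE)
  if (nrow(e)) {
    a <- pmin(e[, 1L], e[, 2L]); b <- pmax(e[, 1L], e[, 2L])
    e <- cbind(a, b)[order(a, b), , drop = FALSE]
  }
  unname(e)
}

#' Count edges within and between communities
#'
#' @param network a [risk_network()].
#' @param structure a [community_structure()] (or assignment vector named by
#'   participant id) partitioning exactly the network's nodes.
#' @return Named integer vector with elements `within` and `between`;
#'   they always sum to the network's edge count.
#' @export
partition_edge_summary <- function(network, structure) {
  memb <- as_membership(structure, network)
  e <- igraph::as_edgelist(network$graph, names = TRUE)
  within <- sum(memb[e[, 1L]] == memb[e[, 2L]])
  c(within = within, between = nrow(e) - within)
}

## Coerce a community_structure or named vector to a membership vector
## aligned with (and validated against) the network's nodes.
as_membership <- function(structure, network) {
  memb <- if (inherits(structure, "community_structure"))
    structure$assignment else structure
  ids <- network_ids(network)
  if (is.null(names(memb))) {
    if (length(memb) != length(ids))
      stop("unnamed assignment must have one entry per node")
    names(memb) <- ids
  }
  absent <- setdiff(ids, names(memb))
  if (length(absent))
    stop("node(s) absent from the partition: ", paste(absent, collapse = ", "))
  memb[ids]
}
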
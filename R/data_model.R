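#' netrewire: condition-specific interactomes and differential rewiring
#'
#' Builds condition-specific protein-protein interaction networks (PPINs)
#' from expression data via domain-resolved pruning, detects significantly
#' rewired interactions between two sample groups, and attributes them to a
#' minimal set of transcriptomic changes.
#'
#' @keywords internal
"_PACKAGE"

# Reserved family name for proteins/edges without documented domain support.
DUMMY_FAMILY <- "DUMMY"

#' Canonical undirected edge
#'
#' Returns the two endpoints of an undirected edge in canonical (sorted)
#' order, so that `(a, b)` and `(b, a)` denote the same edge. Self-loops are
#' rejected: a protein interaction network here is a simple undirected graph.
#'
#' @param a,b Non-empty character scalars, the two endpoint identifiers.
#' @return A character vector of length 2, `c(from, to)` with `from < to`.
#' @examples
#' canonical_edge("P2", "P1")  # c("P1", "P2")
#' @export
canonical_edge <- function(a, b) {
  check_node_id(a)
  check_node_id(b)
  if (a == b) {
    stop("self-loop rejected: '", a, "'", call. = FALSE)
  }
  if (a < b) c(a, b) else c(b, a)
}

check_node_id <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop("node identifiers must be non-empty strings", call. = FALSE)
  }
  invisible(x)
}

# Vectorised canonicalisation of endpoint pairs. Errors on self-loops and
# empty identifiers.
canonicalize_pairs <- function(from, to) {
  from <- as.character(from)
  to <- as.character(to)
  bad <- is.na(from) | is.na(to) | !nzchar(from) | !nzchar(to)
  if (any(bad)) {
    stop("node identifiers must be non-empty strings", call. = FALSE)
  }
  loops <- from == to
  if (any(loops)) {
    stop("self-loop rejected: '", from[which(loops)[1L]], "'", call. = FALSE)
  }
  swap <- from > to
  data.frame(
    from = ifelse(swap, to, from),
    to = ifelse(swap, from, to),
    stringsAsFactors = FALSE
  )
}

edge_key <- function(from, to) paste(from, to, sep = "\t")

#' Construct an undirected interaction network
#'
#' A network is a set of nodes and a set of canonical undirected edges with
#' an optional non-negative weight per edge. The level tag distinguishes
#' protein-level networks (PPIN) from domain-level networks (DDIN). Edges
#' are canonicalised, de-duplicated (first weight wins) and stored sorted,
#' so two networks with the same edge set compare identical.
#'
#' Weights are carried through reading and writing verbatim but are never
#' used by any statistic in this package.
#'
#' @param from,to Character vectors of endpoint identifiers (recycled
#'   pairwise; may be empty for an edgeless network).
#' @param weight Optional numeric vector of non-negative edge weights.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node identifiers; endpoints are always included.
#' @param level `"protein"` or `"domain"`.
#' @return An object of class `ppi_network` with elements `edges` (a
#'   data.frame with columns `from`, `to`, `weight`), `nodes` and `level`.
#' @examples
#' net <- ppi_network(c("P1", "P3"), c("P2", "P2"))
#' net$edges
#' @export
ppi_network <- function(from = character(), to = character(), weight = NULL,
                        nodes = NULL, level = c("protein", "domain")) {
  level <- match.arg(level)
  stopifnot(length(from) == length(to))
  edges <- canonicalize_pairs(from, to)
  if (is.null(weight)) {
    edges$weight <- rep(NA_real_, nrow(edges))
  } else {
    weight <- as.numeric(weight)
    stopifnot(length(weight) == nrow(edges))
    if (any(!is.na(weight) & weight < 0)) {
      stop("edge weights must be non-negative", call. = FALSE)
    }
    edges$weight <- weight
  }
  key <- edge_key(edges$from, edges$to)
  keep <- !duplicated(key)
  edges <- edges[keep, , drop = FALSE]
  edges <- edges[order(key[keep]), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  if (any(is.na(nodes) | !nzchar(nodes))) {
    stop("node identifiers must be non-empty strings", call. = FALSE)
  }
  structure(
    list(edges = edges, nodes = nodes, level = level),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<%s-level network: %d nodes, %d edges>\n",
    x$level, length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

edge_keys <- function(net) edge_key(net$edges$from, net$edges$to)

#' Number of edges in a network
#'
#' @param net A [ppi_network].
#' @return Integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

# Subset a network to the edges whose canonical keys are in `keys`.
subset_network <- function(net, keys) {
  keep <- edge_keys(net) %in% keys
  edges <- net$edges[keep, , drop = FALSE]
  ppi_network(edges$from, edges$to, weight = edges$weight, level = net$level)
}

#' Edge difference between two networks
#'
#' Splits the symmetric difference of two same-level networks into the edges
#' lost (present in `netA`, absent from `netB`) and gained (the reverse).
#'
#' @param netA,netB `ppi_network` objects with matching `level`.
#' @return A list with data.frames `lost` and `gained` (columns `from`,
#'   `to`, `weight`); the two sets are disjoint by construction.
#' @examples
#' a <- ppi_network(c("a", "b"), c("b", "c"))
#' b <- ppi_network(c("a", "c"), c("b", "d"))
#' edge_difference(a, b)
#' @export
edge_difference <- function(netA, netB) {
  stopifnot(inherits(netA, "ppi_network"), inherits(netB, "ppi_network"))
  if (!identical(netA$level, netB$level)) {
    stop("cannot compare networks at different levels (",
         netA$level, " vs ", netB$level, ")", call. = FALSE)
  }
  ka <- edge_keys(netA)
  kb <- edge_keys(netB)
  lost <- netA$edges[!ka %in% kb, , drop = FALSE]
  gained <- netB$edges[!kb %in% ka, , drop = FALSE]
  rownames(lost) <- rownames(gained) <- NULL
  list(lost = lost, gained = gained)
}
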
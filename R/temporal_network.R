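#' Temporal network: a simple undirected graph with edge arrival order
#'
#' A `temporal_network` stores the final topology of a grown network together
#' with whatever is known about its history: the fine-grained arrival
#' position of every edge (rows of `edges` are stored in arrival order, so
#' edge `i` arrived at position `i`), and/or a coarse snapshot label per
#' edge. Node identifiers are opaque strings; the node set may include
#' isolated nodes.
#'
#' @param edges two-column character matrix (or data.frame) of undirected
#'   edges, one row per edge, rows in arrival order.
#' @param nodes optional character vector of node ids; defaults to the ids
#'   appearing in `edges`. Must be a superset of the edge endpoints.
#' @param snapshot optional integer vector, one label per edge, non-decreasing
#'   along arrival order (coarse-grained history).
#' @param node_labels optional named character vector mapping node id to a
#'   category label (used for meso-level analysis).
#' @return an object of class `temporal_network` with fields `nodes`,
#'   `edges`, `snapshot`, `node_labels`.
#' @examples
#' net <- temporal_network(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
#' n_edges(net)
#' @export
temporal_network <- function(edges, nodes = NULL, snapshot = NULL,
                             node_labels = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(dim(edges)) || ncol(edges) != 2)
    stop("`edges` must be a two-column matrix of node pairs")
  edges <- matrix(as.character(edges), ncol = 2)
  if (any(grepl("\t", edges))) stop("node ids must not contain tab characters")
  if (any(edges[, 1] == edges[, 2])) {
    bad <- which(edges[, 1] == edges[, 2])[1]
    stop("self-loop at edge ", bad, " (", edges[bad, 1], ")")
  }
  keys <- edge_key(edges[, 1], edges[, 2])
  if (anyDuplicated(keys)) {
    bad <- which(duplicated(keys))[1]
    stop("duplicate edge at position ", bad, ": ", gsub("\t", "--", keys[bad]))
  }
  ids <- unique(as.vector(t(edges)))
  if (is.null(nodes)) nodes <- ids
  else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node ids")
    if (!all(ids %in% nodes)) stop("edge endpoints missing from `nodes`")
  }
  if (!is.null(snapshot)) {
    snapshot <- as.integer(snapshot)
    if (length(snapshot) != nrow(edges))
      stop("`snapshot` must have one label per edge")
    if (is.unsorted(snapshot))
      stop("snapshot labels must be non-decreasing along arrival order")
    if (min(snapshot) < 1L) stop("snapshot labels must be >= 1")
  }
  if (!is.null(node_labels)) {
    if (is.null(names(node_labels))) stop("`node_labels` must be named by node id")
    node_labels <- vapply(node_labels, as.character, "")
  }
  structure(
    list(nodes = nodes, edges = edges, snapshot = snapshot,
         node_labels = node_labels),
    class = "temporal_network")
}

edge_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "\t")
}

#' @export
print.temporal_network <- function(x, ...) {
  cat("<temporal_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges", sep = "")
  if (!is.null(x$snapshot))
    cat(", ", max(x$snapshot), " snapshots", sep = "")
  if (!is.null(x$node_labels)) cat(", node labels present")
  cat("\n")
  invisible(x)
}

#' Number of edges of a temporal network
#' @param net a `temporal_network`.
#' @return integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' True arrival positions of the edges
#'
#' Edges are stored in arrival order, so the fine-grained ground-truth
#' sequence is simply `1:E`.
#' @param net a `temporal_network`.
#' @return integer vector of arrival positions, one per edge.
#' @export
arrival_order <- function(net) seq_len(nrow(net$edges))

#' Convert to an igraph graph
#' @param net a `temporal_network`.
#' @return an undirected `igraph` graph whose vertex order matches
#'   `net$nodes`.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  idx <- match(as.vector(t(net$edges)), net$nodes)
  igraph::add_edges(g, idx)
}

#' Coarsen a fine-grained arrival sequence into snapshots
#'
#' Splits the arrival sequence into `n_snapshots` contiguous blocks of
#' near-equal size; when sizes cannot be equal the earlier blocks receive
#' the remainder. The fine arrival order is retained (row order) so that
#' restorations can still be evaluated against it.
#'
#' @param net a `temporal_network` with fine-grained arrival order.
#' @param n_snapshots number of snapshots, between 1 and the edge count.
#' @return the network with snapshot labels attached.
#' @examples
#' net <- generate_ba(10, 1, seed = 1)
#' coarsen_to_snapshots(net, 3)$snapshot
#' @export
coarsen_to_snapshots <- function(net, n_snapshots) {
  E <- n_edges(net)
  n_snapshots <- as.integer(n_snapshots)
  if (n_snapshots < 1L || n_snapshots > E)
    stop("`n_snapshots` must be between 1 and the number of edges (", E, ")")
  sizes <- snapshot_sizes(E, n_snapshots)
  net$snapshot <- rep.int(seq_len(n_snapshots), sizes)
  net
}

snapshot_sizes <- function(E, n) {
  base <- E %/% n
  rem <- E %% n
  base + as.integer(seq_len(n) <= rem)
}

#' Count edge pairs with distinguishable arrival order
#'
#' With fine-grained history every unordered pair is distinguishable,
#' `E(E-1)/2` in total. With snapshots only, pairs inside the same snapshot
#' are indistinguishable, leaving
#' `E(E-1)/2 - sum_k l_k (l_k - 1) / 2` pairs for snapshot sizes `l_k`.
#'
#' @param net a `temporal_network`.
#' @return number of distinguishable unordered edge pairs.
#' @export
n_distinguishable_pairs <- function(net) {
  E <- n_edges(net)
  total <- E * (E - 1) / 2
  if (is.null(net$snapshot)) return(total)
  lk <- tabulate(net$snapshot)
  total - sum(lk * (lk - 1) / 2)
}
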
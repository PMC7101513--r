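#' Interaction network container
#'
#' An `interaction_network` is an undirected simple graph over gene symbols:
#' no self-loops, no duplicate edges, node set may contain isolated genes.
#' Gene symbols are opaque, case-sensitive strings; no alias resolution is
#' attempted. Edges may carry an optional confidence score in \[0, 1\]
#' (e.g. a STRING combined score rescaled to 0-1), which is stored but never
#' used as a shortest-path weight.
#'
#' @param nodes character vector of gene symbols (non-empty, unique).
#' @param edges two-column character matrix (or data.frame) of endpoints;
#'   rows are unordered pairs. Reversed and repeated rows collapse to one
#'   edge; self-loop rows are an error here (dropped with a warning only at
#'   the file-reading layer, see [read_edge_list()]).
#' @param score optional numeric vector of per-edge confidences in \[0, 1\],
#'   one per row of `edges` (kept for the first occurrence of each edge).
#' @param name free-text label for the network.
#'
#' @return An object of class `interaction_network`: a list with elements
#'   `nodes` (character), `edges` (2-column character matrix with
#'   lexicographically ordered endpoints, deduplicated), `score` (numeric or
#'   `NULL`) and `name`.
#' @examples
#' net <- interaction_network(c("A", "B", "C"),
#'                            rbind(c("A", "B"), c("B", "C")))
#' n_edges(net)
#' @export
interaction_network <- function(nodes, edges = NULL, score = NULL, name = "") {
  nodes <- as.character(nodes)
  if (length(nodes) == 0L) stop("network must have at least one node")
  if (anyNA(nodes) || any(!nzchar(nodes))) {
    stop("node names must be non-empty strings")
  }
  if (anyDuplicated(nodes)) stop("duplicate node names: ",
                                 paste(unique(nodes[duplicated(nodes)]),
                                       collapse = ", "))
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2L,
                 dimnames = list(NULL, c("node1", "node2")))
    out <- structure(list(nodes = nodes, edges = em, score = NULL,
                          name = name),
                     class = "interaction_network")
    return(out)
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have exactly two columns")
  storage.mode(edges) <- "character"
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  unknown <- setdiff(c(edges), nodes)
  if (length(unknown)) stop("edge endpoint not in node set: ",
                            paste(unknown, collapse = ", "))
  if (!is.null(score)) {
    score <- as.numeric(score)
    if (length(score) != nrow(edges)) {
      stop("score must have one value per edge row")
    }
    if (any(is.na(score)) || any(score < 0 | score > 1)) {
      stop("scores must be in [0, 1]")
    }
  }
  # canonical unordered form: endpoints sorted within each row
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, c(2L, 1L)]
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  keep <- !duplicated(key)
  edges <- edges[keep, , drop = FALSE]
  if (!is.null(score)) score <- score[keep]
  ord <- order(edges[, 1L], edges[, 2L], method = "radix")
  edges <- edges[ord, , drop = FALSE]
  if (!is.null(score)) score <- score[ord]
  colnames(edges) <- c("node1", "node2")
  structure(list(nodes = nodes, edges = edges, score = score, name = name),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  iso <- sum(node_degrees(x) == 0L)
  cat(sprintf("<interaction_network%s: %d nodes, %d edges, %d isolated>\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              length(x$nodes), nrow(x$edges), iso))
  invisible(x)
}

#' Number of nodes / edges
#' @param net an `interaction_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Per-node degree as a named integer vector
#'
#' @param net an `interaction_network`.
#' @return named integer vector over all nodes (isolated nodes have 0),
#'   in the network's node order.
#' @export
node_degrees <- function(net) {
  d <- integer(length(net$nodes))
  names(d) <- net$nodes
  if (nrow(net$edges)) {
    t1 <- table(factor(net$edges[, 1L], levels = net$nodes))
    t2 <- table(factor(net$edges[, 2L], levels = net$nodes))
    d <- as.integer(t1 + t2)
    names(d) <- net$nodes
  }
  d
}

#' Convert to / from igraph
#'
#' Used internally for component extraction and by the synthetic generator;
#' exported because it is handy for plotting.
#'
#' @param net an `interaction_network`.
#' @return `as_igraph()`: an undirected [igraph::graph]; isolated nodes kept.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' Largest connected component
#'
#' Extracts the main connected component, the analysis frame used throughout
#' the screening pipeline (centrality statistics and the hub/bottleneck
#' thresholds are computed over this component, with isolated genes and minor
#' components set aside and reported as counts).
#'
#' Ties on component size are broken by the lexicographically smallest member
#' so the result is deterministic.
#'
#' @param net an `interaction_network`.
#' @return an `interaction_network` restricted to the largest component.
#' @export
main_component <- function(net) {
  if (n_edges(net) == 0L) {
    return(interaction_network(sort(net$nodes)[1L], name = net$name))
  }
  comp <- igraph::components(as_igraph(net))
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    leaders <- vapply(best, function(i) {
      min(net$nodes[comp$membership == i])
    }, character(1))
    best <- best[order(leaders)][1L]
  }
  keep <- net$nodes[comp$membership == best]
  induce_subnetwork(net, sort(keep))
}

#' Node-induced subnetwork
#'
#' Keeps exactly the named genes and every edge whose two endpoints are both
#' in the list. Used to build the central-gene sub-network that is then
#' re-ranked.
#'
#' @param net an `interaction_network`.
#' @param central character vector of gene symbols, all present in `net`.
#' @return an `interaction_network` over `central` (in the given order).
#' @export
induce_subnetwork <- function(net, central) {
  central <- as.character(central)
  unknown <- setdiff(central, net$nodes)
  if (length(unknown)) stop("unknown gene(s) in central list: ",
                            paste(unknown, collapse = ", "))
  if (anyDuplicated(central)) stop("central list has duplicates")
  keep <- net$edges[, 1L] %in% central & net$edges[, 2L] %in% central
  interaction_network(central, net$edges[keep, , drop = FALSE],
                      score = if (is.null(net$score)) NULL else
                        net$score[keep],
                      name = net$name)
}
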
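#' Typed, signed directed action graph
#'
#' Container for regulatory relations between central genes: directed edges
#' typed as `expression` (carrying an `up`/`down` sign — the drawn round or
#' bar tip of a regulation arrow), `activation`, or `inhibition` (both
#' unsigned, `sign = "none"`). The node list is the full central-gene set;
#' genes with no edge in a layer are *isolated in that layer*, which is
#' meaningful (participation counts exclude them).
#'
#' @param nodes character vector of gene symbols.
#' @param edges data.frame with columns `source`, `target`, `action`,
#'   `sign` (see [read_actions()] for the validation rules).
#' @return object of class `action_graph`: list with `nodes` and `edges`.
#' @export
action_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        action = character(0), sign = character(0),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  validate_action_edges(edges)
  unknown <- setdiff(unique(c(edges$source, edges$target)), nodes)
  if (length(unknown)) stop("edge endpoint not in node set: ",
                            paste(unknown, collapse = ", "))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "action_graph")
}

#' @export
print.action_graph <- function(x, ...) {
  cnt <- table(factor(x$edges$action, levels = .ACTIONS))
  cat(sprintf(
    "<action_graph: %d nodes; %d expression, %d activation, %d inhibition edges>\n",
    length(x$nodes), cnt[["expression"]], cnt[["activation"]],
    cnt[["inhibition"]]))
  invisible(x)
}

#' Restrict an action graph to one action layer
#'
#' Keeps only edges of the named type; the node set is unchanged because
#' isolation within a layer is itself a finding.
#'
#' @param graph an `action_graph`.
#' @param action one of `"expression"`, `"activation"`, `"inhibition"`.
#' @return an `action_graph` with edges of that type only.
#' @export
action_layer <- function(graph, action) {
  if (!action %in% .ACTIONS) stop("unknown action type: ", action)
  action_graph(graph$nodes, graph$edges[graph$edges$action == action, ])
}

#' Layer participation
#'
#' A gene participates in a layer when it is non-isolated there, i.e. has at
#' least one incident edge of that type (in either direction). Returns the
#' participant count and the percentage of the node list, rounded to the
#' nearest integer as conventionally reported (the exact fraction is also
#' returned).
#'
#' @param graph an `action_graph`.
#' @param action layer name.
#' @return list with `participants` (sorted character vector), `count`,
#'   `percent` (integer-rounded), and `fraction` (unrounded).
#' @export
participation <- function(graph, action) {
  if (length(graph$nodes) == 0L) stop("action graph has no nodes")
  lay <- action_layer(graph, action)
  touched <- sort(unique(c(lay$edges$source, lay$edges$target)))
  frac <- length(touched) / length(graph$nodes)
  list(participants = touched,
       count = length(touched),
       percent = as.integer(round(100 * frac)),
       fraction = frac)
}

#' Per-gene regulatory tally in the expression layer
#'
#' Counts a gene's outgoing expression edges by sign and the distinct genes
#' it regulates (a target reached by both an up- and a down-edge is counted
#' once), plus its incoming expression edge count and whether it
#' participates in the layer at all. These tallies always satisfy
#' `max(up_out, down_out) <= unique_targets <= up_out + down_out`.
#'
#' @param graph an `action_graph`.
#' @param gene gene symbol, must be in the node list.
#' @return list with `gene`, `up_out`, `down_out`, `unique_targets`,
#'   `in_degree`, `participates`.
#' @export
regulatory_tally <- function(graph, gene) {
  if (!gene %in% graph$nodes) stop("unknown gene: ", gene)
  lay <- action_layer(graph, "expression")$edges
  out <- lay[lay$source == gene, ]
  list(gene = gene,
       up_out = sum(out$sign == "up"),
       down_out = sum(out$sign == "down"),
       unique_targets = length(unique(out$target)),
       in_degree = sum(lay$target == gene),
       participates = gene %in% c(lay$source, lay$target))
}

#' Weakly connected components of the inhibition layer
#'
#' The inhibition network typically splits into small separate parts; this
#' returns them as node sets under weak connectivity (edge direction
#' ignored), excluding layer-isolated genes, ordered by size descending and
#' then by lexicographically smallest member.
#'
#' @param graph an `action_graph`.
#' @return list of sorted character vectors (possibly empty).
#' @export
inhibition_components <- function(graph) {
  lay <- action_layer(graph, "inhibition")$edges
  if (nrow(lay) == 0L) return(list())
  g <- igraph::graph_from_data_frame(lay[, c("source", "target")],
                                     directed = TRUE)
  comp <- igraph::components(g, mode = "weak")
  parts <- split(names(comp$membership), comp$membership)
  parts <- lapply(unname(parts), sort)
  leaders <- vapply(parts, `[`, character(1), 1L)
  parts[order(-lengths(parts), leaders)]
}

#' Reciprocal pairs within a layer
#'
#' Unordered pairs (u, v) with edges in both directions within the named
#' layer — e.g. mutual inhibition between two transcription factors.
#'
#' @param graph an `action_graph`.
#' @param action layer name.
#' @return data.frame with columns `gene1`, `gene2`
#'   (`gene1 < gene2` lexicographically), sorted; zero rows when none.
#' @export
reciprocal_pairs <- function(graph, action) {
  lay <- action_layer(graph, action)$edges
  empty <- data.frame(gene1 = character(0), gene2 = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(lay) == 0L) return(empty)
  pairs <- unique(lay[, c("source", "target")])
  fwd <- paste(pairs$source, pairs$target, sep = "\r")
  rev <- paste(pairs$target, pairs$source, sep = "\r")
  both <- pairs[fwd %in% rev & pairs$source < pairs$target, ]
  if (nrow(both) == 0L) return(empty)
  out <- data.frame(gene1 = both$source, gene2 = both$target,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene1, out$gene2), ]
  rownames(out) <- NULL
  out
}

#' Summarize all three action layers
#'
#' Convenience wrapper used by the pipeline report: participation per layer,
#' the top regulators of the expression layer (by unique targets), reciprocal
#' pairs per layer, and the inhibition components.
#'
#' @param graph an `action_graph`.
#' @param top_n number of top regulators to keep (default 5).
#' @return list keyed by layer plus `top_regulators` and
#'   `inhibition_components`.
#' @export
summarize_actions <- function(graph, top_n = 5L) {
  layers <- lapply(stats::setNames(.ACTIONS, .ACTIONS), function(a) {
    p <- participation(graph, a)
    list(count = p$count, percent = p$percent,
         participants = p$participants,
         reciprocal_pairs = reciprocal_pairs(graph, a))
  })
  tallies <- lapply(graph$nodes, function(g) regulatory_tally(graph, g))
  ut <- vapply(tallies, `[[`, numeric(1), "unique_targets")
  ord <- order(-ut, vapply(tallies, `[[`, character(1), "gene"))
  top <- tallies[ord[seq_len(min(top_n, length(tallies)))]]
  top <- top[vapply(top, `[[`, numeric(1), "unique_targets") > 0]
  list(layers = layers,
       top_regulators = top,
       inhibition_components = inhibition_components(graph))
}
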
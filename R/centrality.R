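#' Degree and normalized betweenness centrality
#'
#' Computes the two node statistics that drive the hub/bottleneck screening:
#' degree (number of incident edges) and betweenness centrality, the latter
#' via Brandes' single-source shortest-path accumulation on the unweighted
#' graph. Raw pair-dependency sums are divided by `(n-1)(n-2)/2` with `n` the
#' total number of nodes of the analyzed network, giving the 0-1 scale
#' reported by Cytoscape's NetworkAnalyzer; path endpoints are excluded.
#' Pairs of nodes in different components contribute nothing. In a network
#' with fewer than 3 nodes every betweenness is 0.
#'
#' Edge confidence scores are never used as weights: shortest paths are hop
#' counts. Nodes are processed in lexicographic order so floating-point
#' accumulation is bit-for-bit reproducible.
#'
#' @param net an [interaction_network()].
#' @return a `centrality_table`: a data.frame with columns `name`, `degree`
#'   (integer), `betweenness` (numeric in \[0, 1\]), one row per node sorted
#'   by degree descending then name ascending, with attribute `n` recording
#'   the node count the statistics were computed over.
#' @examples
#' net <- interaction_network(c("A", "B", "C"),
#'                            rbind(c("A", "B"), c("B", "C")))
#' centrality_table(net)  # B lies on the single A-C shortest path
#' @export
centrality_table <- function(net) {
  deg <- node_degrees(net)
  bc <- betweenness_of_all(net)
  tab <- data.frame(name = net$nodes,
                    degree = as.integer(deg),
                    betweenness = as.numeric(bc[net$nodes]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$degree, tab$name, method = "radix"), ]
  rownames(tab) <- NULL
  attr(tab, "n") <- length(net$nodes)
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' @rdname centrality_table
#' @return `degree_of_all()`: named integer vector of degrees (alias of
#'   [node_degrees()]).
#' @export
degree_of_all <- function(net) node_degrees(net)

#' @rdname centrality_table
#' @return `betweenness_of_all()`: named numeric vector of normalized
#'   betweenness values over all nodes.
#' @export
betweenness_of_all <- function(net) {
  n <- length(net$nodes)
  nodes <- sort(net$nodes)
  cb <- numeric(n)
  names(cb) <- nodes
  if (n < 3L || nrow(net$edges) == 0L) {
    names(cb) <- nodes
    return(cb[net$nodes])
  }
  idx <- seq_len(n)
  names(idx) <- nodes
  adj <- vector("list", n)
  e1 <- idx[net$edges[, 1L]]
  e2 <- idx[net$edges[, 2L]]
  for (k in seq_along(e1)) {
    adj[[e1[k]]] <- c(adj[[e1[k]]], e2[k])
    adj[[e2[k]]] <- c(adj[[e2[k]]], e1[k])
  }
  adj <- lapply(adj, sort)

  cb_num <- numeric(n)
  for (s in idx) {
    # BFS from s with shortest-path counting
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep.int(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    stack <- integer(n); top <- 0L
    queue <- integer(n); qh <- 1L; qt <- 1L
    queue[qt] <- s; qt <- qt + 1L
    while (qh < qt) {
      v <- queue[qh]; qh <- qh + 1L
      top <- top + 1L; stack[top] <- v
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue[qt] <- w; qt <- qt + 1L
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    # dependency accumulation in reverse BFS order
    delta <- numeric(n)
    while (top > 0L) {
      w <- stack[top]; top <- top - 1L
      pw <- preds[[w]]
      if (length(pw)) {
        contrib <- (sigma[pw] / sigma[w]) * (1 + delta[w])
        for (j in seq_along(pw)) {
          delta[pw[j]] <- delta[pw[j]] + contrib[j]
        }
      }
      if (w != s) cb_num[w] <- cb_num[w] + delta[w]
    }
  }
  # each unordered pair counted twice; normalize by (n-1)(n-2)/2
  cb <- cb_num / 2 / ((n - 1) * (n - 2) / 2)
  names(cb) <- nodes
  cb[net$nodes]
}
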
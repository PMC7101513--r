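# Independent betweenness oracle: enumerate every shortest path between
# every node pair (igraph path enumeration) and count interior memberships,
# splitting each pair's unit weight evenly across its shortest paths.
# Normalized by (n-1)(n-2)/2 with n the full node count, endpoints excluded.
brute_force_betweenness <- function(net) {
  n <- length(net$nodes)
  nodes <- sort(net$nodes)
  bc <- stats::setNames(numeric(n), nodes)
  if (n < 3L) return(bc[net$nodes])
  g <- as_igraph(net)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = nodes[i], to = nodes[j]))
      vp <- if (!is.null(paths$vpaths)) paths$vpaths else paths$res
      if (length(vp) == 0L) next
      for (p in vp) {
        nm <- names(p)
        if (length(nm) > 2L) {
          interior <- nm[-c(1L, length(nm))]
          bc[interior] <- bc[interior] + 1 / length(vp)
        }
      }
    }
  }
  (bc / ((n - 1) * (n - 2) / 2))[net$nodes]
}

# Erdos-Renyi-style random test network over letter-named nodes
random_network <- function(n, p = 0.4) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  interaction_network(nodes, pairs[keep, , drop = FALSE])
}

triangle_net <- function() {
  interaction_network(c("A", "B", "C"),
                      rbind(c("A", "B"), c("B", "C"), c("C", "A")))
}

star_net <- function(k = 5L) {
  leaves <- sprintf("L%d", seq_len(k))
  interaction_network(c("H", leaves), cbind("H", leaves))
}

path_net <- function() {
  interaction_network(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
}
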
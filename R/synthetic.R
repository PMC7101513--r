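#' Generator configuration
#'
#' Bundles the parameters of the synthetic-network generator. The defaults
#' emulate the shape of a STRING disease-gene pull of the kind the screening
#' pipeline targets: 451 genes found, of which 68 come back with no
#' interaction (isolated) and 383 form one scale-free main component grown
#' by preferential attachment with 2 edges per incoming node.
#'
#' @param n_total total number of genes (default 451).
#' @param n_isolated number of degree-0 genes (default 68).
#' @param attachment edges added per new node during preferential-attachment
#'   growth (default 2).
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @param n_planted_hubs number of extra high-degree nodes wired in after
#'   growth (default 0); used for screening-recovery experiments.
#' @param planted_hub_degree degree given to each planted hub (default: 15%
#'   of the connected part, at least 20).
#' @param action_config per-layer action edge counts and sign probability,
#'   see [action_config()].
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_total = 451L, n_isolated = 68L,
                             attachment = 2L, seed,
                             n_planted_hubs = 0L,
                             planted_hub_degree = NULL,
                             action_config = ppiscreen::action_config()) {
  if (missing(seed)) stop("seed is mandatory: no hidden entropy")
  n_total <- as.integer(n_total); n_isolated <- as.integer(n_isolated)
  attachment <- as.integer(attachment)
  if (n_isolated >= n_total) stop("n_isolated must be < n_total")
  if (attachment < 1L) stop("attachment must be >= 1")
  n_conn <- n_total - n_isolated
  if (n_conn < 2L) stop("connected part needs >= 2 nodes")
  if (is.null(planted_hub_degree)) {
    planted_hub_degree <- max(20L, ceiling(0.15 * n_conn))
  }
  structure(list(n_total = n_total, n_isolated = n_isolated,
                 attachment = attachment, seed = as.integer(seed),
                 n_planted_hubs = as.integer(n_planted_hubs),
                 planted_hub_degree = as.integer(planted_hub_degree),
                 action_config = action_config),
            class = "generator_config")
}

# evaluate code under a seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a paper-shaped synthetic interaction network
#'
#' Grows a scale-free connected component by preferential attachment
#' (Barabasi-Albert-style growth, via [igraph::sample_pa()]), optionally
#' wires in planted high-degree hub nodes, and appends the configured number
#' of isolated genes. Nodes are named `G0001`, `G0002`, ... with the
#' connected part first. The result is reproducible per seed.
#'
#' @param cfg a [generator_config()].
#' @return an [interaction_network()] with attribute `planted_hubs` naming
#'   any planted hub nodes.
#' @examples
#' net <- generate_paper_like_network(generator_config(seed = 7))
#' sum(node_degrees(net) == 0)  # 68 isolated genes
#' @export
generate_paper_like_network <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n_conn <- cfg$n_total - cfg$n_isolated
  n_grown <- n_conn - cfg$n_planted_hubs
  if (n_grown <= cfg$attachment) stop("too few non-planted connected nodes")
  names_all <- sprintf("G%04d", seq_len(cfg$n_total))
  with_seed(cfg$seed, {
    g <- igraph::sample_pa(n_grown, m = cfg$attachment, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- cbind(names_all[el[, 1L]], names_all[el[, 2L]])
    planted <- character(0)
    if (cfg$n_planted_hubs > 0L) {
      if (cfg$planted_hub_degree > n_grown) {
        stop("planted_hub_degree exceeds available attachment partners")
      }
      planted <- names_all[n_grown + seq_len(cfg$n_planted_hubs)]
      for (h in planted) {
        targets <- sample(names_all[seq_len(n_grown)],
                          cfg$planted_hub_degree)
        edges <- rbind(edges, cbind(h, targets))
      }
    }
    net <- interaction_network(names_all, edges, name = "synthetic")
    attr(net, "planted_hubs") <- planted
    net
  })
}

#' Action-layer sampling configuration
#'
#' Per-layer edge counts and the probability that a sampled expression edge
#' is up-regulating; defaults give an activation-dominant map, sparse
#' inhibition, and a mixed-sign expression layer.
#'
#' @param n_expression,n_activation,n_inhibition random edges per layer.
#' @param p_up probability a sampled expression edge is `up`.
#' @param plants list of planted facts, see [plant_out()],
#'   [plant_isolated()], [plant_reciprocal()].
#' @return list of class `action_config`.
#' @export
action_config <- function(n_expression = 25L, n_activation = 35L,
                          n_inhibition = 8L, p_up = 0.6, plants = list()) {
  structure(list(n_expression = as.integer(n_expression),
                 n_activation = as.integer(n_activation),
                 n_inhibition = as.integer(n_inhibition),
                 p_up = p_up, plants = plants),
            class = "action_config")
}

#' Planted action facts
#'
#' Directives the generator must embed exactly, so downstream tallies have
#' known ground truth. `plant_out()` fixes a gene's outgoing edges in a
#' layer (for expression: `up` up-edges and `down` down-edges with `overlap`
#' targets receiving both; otherwise `n_out` edges); `in_zero = TRUE`
#' additionally forbids incoming edges in that layer. `plant_isolated()`
#' forces a gene to be isolated in a layer; `plant_reciprocal()` forces a
#' mutual pair.
#'
#' @param gene,pair gene symbol(s).
#' @param action layer name.
#' @param up,down,overlap,n_out out-edge counts.
#' @param in_zero forbid incoming edges in the layer.
#' @return a plant directive (list) for [action_config()].
#' @export
plant_out <- function(gene, action, up = 0L, down = 0L, overlap = 0L,
                      n_out = 0L, in_zero = FALSE) {
  structure(list(gene = gene, action = action, up = as.integer(up),
                 down = as.integer(down), overlap = as.integer(overlap),
                 n_out = as.integer(n_out), in_zero = isTRUE(in_zero)),
            class = c("plant_out", "plant"))
}

#' @rdname plant_out
#' @export
plant_isolated <- function(gene, action) {
  structure(list(gene = gene, action = action),
            class = c("plant_isolated", "plant"))
}

#' @rdname plant_out
#' @export
plant_reciprocal <- function(pair, action) {
  stopifnot(length(pair) == 2L)
  structure(list(pair = as.character(pair), action = action),
            class = c("plant_reciprocal", "plant"))
}

#' Sample an action graph over the central genes
#'
#' Draws random typed directed edges among the central genes per the
#' configuration, then embeds any planted facts. Planted facts take
#' precedence: sampled edges that would violate them (extra out-edges from a
#' gene with a fixed out-tally, any edge touching a gene planted isolated,
#' incoming edges to an `in_zero` gene) are never drawn. Every plant is
#' re-verified through the analysis functions after generation and a
#' violation is an error, so a returned graph always honours its plants.
#'
#' @param net an `interaction_network` (the central genes must belong to
#'   it).
#' @param central character vector of central genes.
#' @param cfg an [action_config()].
#' @param seed integer seed.
#' @return an [action_graph()] over `central`.
#' @export
annotate_actions <- function(net, central, cfg = action_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  unknown <- setdiff(central, net$nodes)
  if (length(unknown)) stop("central gene not in network: ",
                            paste(unknown, collapse = ", "))
  plants <- cfg$plants
  with_seed(seed, {
    planted_edges <- do.call(rbind, lapply(plants, plant_edges,
                                           central = central))
    edges <- planted_edges
    frozen_src <- vapply(Filter(function(p) inherits(p, "plant_out"),
                                plants),
                         function(p) paste(p$gene, p$action), character(1))
    in_zero <- vapply(Filter(function(p) inherits(p, "plant_out") &&
                               p$in_zero, plants),
                      function(p) paste(p$gene, p$action), character(1))
    iso <- vapply(Filter(function(p) inherits(p, "plant_isolated"), plants),
                  function(p) paste(p$gene, p$action), character(1))
    n_per <- c(expression = cfg$n_expression, activation = cfg$n_activation,
               inhibition = cfg$n_inhibition)
    for (act in .ACTIONS) {
      have <- if (is.null(edges)) 0L else sum(edges$action == act)
      need <- n_per[[act]] - have
      tries <- 0L
      while (need > 0L && tries < 200L * n_per[[act]]) {
        tries <- tries + 1L
        uv <- sample(central, 2L)
        sgn <- if (act == "expression") {
          if (stats::runif(1) < cfg$p_up) "up" else "down"
        } else "none"
        if (paste(uv[1L], act) %in% c(frozen_src, iso)) next
        if (paste(uv[2L], act) %in% c(iso, in_zero)) next
        cand <- data.frame(source = uv[1L], target = uv[2L],
                           action = act, sign = sgn,
                           stringsAsFactors = FALSE)
        key <- function(d) do.call(paste, c(d, sep = "\r"))
        if (!is.null(edges) && key(cand) %in% key(edges)) next
        edges <- rbind(edges, cand)
        need <- need - 1L
      }
    }
    graph <- action_graph(central, edges)
    verify_plants(graph, plants)
    graph
  })
}

# expand one plant directive into concrete edges
plant_edges <- function(p, central) {
  UseMethod("plant_edges")
}

#' @export
plant_edges.plant_isolated <- function(p, central) NULL

#' @export
plant_edges.plant_reciprocal <- function(p, central) {
  data.frame(source = c(p$pair[1L], p$pair[2L]),
             target = c(p$pair[2L], p$pair[1L]),
             action = p$action, sign = "none", stringsAsFactors = FALSE)
}

#' @export
plant_edges.plant_out <- function(p, central) {
  pool <- setdiff(central, p$gene)
  if (p$action == "expression") {
    n_unique <- p$up + p$down - p$overlap
    if (p$overlap > min(p$up, p$down)) {
      stop("plant for ", p$gene, ": overlap exceeds up/down counts")
    }
    if (n_unique > length(pool)) {
      stop("plant for ", p$gene, ": ", n_unique,
           " targets demanded among ", length(pool), " available genes")
    }
    targets <- sample(pool, n_unique)
    both <- targets[seq_len(p$overlap)]
    up_only <- targets[p$overlap + seq_len(p$up - p$overlap)]
    down_only <- targets[p$up + seq_len(p$down - p$overlap)]
    data.frame(source = p$gene,
               target = c(both, up_only, both, down_only),
               action = "expression",
               sign = rep(c("up", "down"), c(p$up, p$down)),
               stringsAsFactors = FALSE)
  } else {
    if (p$n_out > length(pool)) {
      stop("plant for ", p$gene, ": ", p$n_out,
           " targets demanded among ", length(pool), " available genes")
    }
    data.frame(source = p$gene, target = sample(pool, p$n_out),
               action = p$action, sign = "none", stringsAsFactors = FALSE)
  }
}

# post-hoc verification: generation fails loudly if a plant is violated
verify_plants <- function(graph, plants) {
  for (p in plants) {
    if (inherits(p, "plant_isolated")) {
      if (p$gene %in% participation(graph, p$action)$participants) {
        stop("planted isolation violated for ", p$gene, " in ", p$action)
      }
    } else if (inherits(p, "plant_reciprocal")) {
      rp <- reciprocal_pairs(graph, p$action)
      pr <- sort(p$pair)
      if (!any(rp$gene1 == pr[1L] & rp$gene2 == pr[2L])) {
        stop("planted reciprocal pair missing: ",
             paste(pr, collapse = "-"))
      }
    } else if (inherits(p, "plant_out")) {
      if (p$action == "expression") {
        t <- regulatory_tally(graph, p$gene)
        ok <- t$up_out == p$up && t$down_out == p$down &&
          t$unique_targets == p$up + p$down - p$overlap &&
          (!p$in_zero || t$in_degree == 0L)
        if (!ok) stop("planted expression tally violated for ", p$gene)
      } else {
        lay <- action_layer(graph, p$action)$edges
        if (sum(lay$source == p$gene) != p$n_out ||
            (p$in_zero && any(lay$target == p$gene))) {
          stop("planted out-degree violated for ", p$gene)
        }
      }
    }
  }
  invisible(TRUE)
}
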
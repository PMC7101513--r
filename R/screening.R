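#' Hub selection: degree above mean + SD
#'
#' Hubs are the nodes whose degree strictly exceeds the network mean degree
#' plus one standard deviation. The SD is the population standard deviation
#' (divisor `n`); both the strictness and the divisor are configurable but
#' pinned here so hub lists are reproducible. When every degree is equal the
#' threshold equals the common value and the hub list is empty.
#'
#' An alternative `"top_k"` rule takes the `k` highest-degree nodes instead;
#' it is the rule to use when screening a printed candidate table (a
#' fixed-size pool of already-selected central genes) rather than a whole
#' network.
#'
#' @param table a `centrality_table`.
#' @param rule `"mean_sd"` (default) or `"top_k"`.
#' @param k pool size for `rule = "top_k"`.
#' @param strict use strict inequality (default TRUE).
#' @return character vector of hub names sorted by degree descending then
#'   name ascending, with attribute `threshold` (the mean + SD cutoff, or
#'   the smallest selected degree under `"top_k"`).
#' @export
select_hubs <- function(table, rule = c("mean_sd", "top_k"), k = 20L,
                        strict = TRUE) {
  rule <- match.arg(rule)
  if (nrow(table) == 0L) stop("empty centrality table")
  ord <- order(-table$degree, table$name, method = "radix")
  tab <- table[ord, ]
  if (rule == "mean_sd") {
    d <- tab$degree
    thr <- mean(d) + pop_sd(d)
    sel <- if (strict) tab$degree > thr else tab$degree >= thr
    hubs <- tab$name[sel]
  } else {
    k <- min(as.integer(k), nrow(tab))
    hubs <- tab$name[seq_len(k)]
    thr <- tab$degree[k]
  }
  attr(hubs, "threshold") <- thr
  hubs
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Bottleneck selection: top fraction by betweenness
#'
#' Bottlenecks are the top 5% of nodes by betweenness centrality. The count
#' is `ceiling(frac * n)` with `n` the number of rows screened (so 383 nodes
#' yield 20 bottlenecks); ties at the boundary are broken by higher degree
#' and then name ascending, making the list deterministic.
#'
#' @param table a `centrality_table`.
#' @param frac fraction of nodes to take (default 0.05).
#' @param k explicit count overriding `frac` if given.
#' @return character vector of bottleneck names ordered by betweenness
#'   descending (degree, then name on ties), with attribute `count`.
#' @export
select_bottlenecks <- function(table, frac = 0.05, k = NULL) {
  if (nrow(table) == 0L) stop("empty centrality table")
  count <- if (is.null(k)) ceiling(frac * nrow(table)) else as.integer(k)
  count <- min(count, nrow(table))
  ord <- order(-table$betweenness, -table$degree, table$name,
               method = "radix")
  bn <- table$name[ord][seq_len(count)]
  attr(bn, "count") <- count
  bn
}

#' Hub / bottleneck / hub-bottleneck screening
#'
#' Composes [select_hubs()] and [select_bottlenecks()]; hub-bottlenecks are
#' their intersection and the central genes their union. The result carries
#' the thresholds that produced it so every reported list is reproducible.
#'
#' @param table a `centrality_table` over the analyzed (main-component)
#'   network, or over a printed candidate pool with `hub_rule = "top_k"`.
#' @param hub_rule,hub_k,strict passed to [select_hubs()].
#' @param bottleneck_frac,bottleneck_k passed to [select_bottlenecks()].
#' @return object of class `screening_result`: list with `hubs`,
#'   `bottlenecks`, `hub_bottlenecks`, `central` (ordered gene vectors),
#'   `degree_threshold`, `bottleneck_count`, and `n`. Ordering of
#'   `hub_bottlenecks` and `central` is degree descending, then betweenness
#'   descending, then name ascending.
#' @examples
#' tab <- table1_fixture()
#' res <- screen(tab, hub_rule = "top_k", hub_k = 20, bottleneck_k = 20)
#' res$hub_bottlenecks
#' @export
screen <- function(table, hub_rule = c("mean_sd", "top_k"), hub_k = 20L,
                   strict = TRUE, bottleneck_frac = 0.05,
                   bottleneck_k = NULL) {
  hub_rule <- match.arg(hub_rule)
  hubs <- select_hubs(table, rule = hub_rule, k = hub_k, strict = strict)
  bottlenecks <- select_bottlenecks(table, frac = bottleneck_frac,
                                    k = bottleneck_k)
  ord <- order(-table$degree, -table$betweenness, table$name,
               method = "radix")
  ranked <- table$name[ord]
  hb <- ranked[ranked %in% hubs & ranked %in% bottlenecks]
  central <- ranked[ranked %in% hubs | ranked %in% bottlenecks]
  res <- structure(
    list(hubs = as.character(hubs),
         bottlenecks = as.character(bottlenecks),
         hub_bottlenecks = hb,
         central = central,
         degree_threshold = attr(hubs, "threshold"),
         bottleneck_count = attr(bottlenecks, "count"),
         n = nrow(table)),
    class = "screening_result")
  stopifnot(length(res$central) ==
              length(res$hubs) + length(res$bottlenecks) -
              length(res$hub_bottlenecks))
  res
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(
    "<screening_result: %d hubs (degree threshold %.3f), %d bottlenecks, %d hub-bottlenecks, %d central of %d>\n",
    length(x$hubs), x$degree_threshold, length(x$bottlenecks),
    length(x$hub_bottlenecks), length(x$central), x$n))
  if (length(x$hub_bottlenecks)) {
    cat("hub-bottlenecks:", paste(x$hub_bottlenecks, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Re-rank the central-gene sub-network
#'
#' Recomputes degree and normalized betweenness within the induced
#' sub-network (normalization uses the sub-network size) and ranks by degree
#' descending, betweenness descending, then name ascending. Each gene's rank
#' in the original full-network table is attached, so promotion or demotion
#' relative to the full network is visible at a glance.
#'
#' @param sub an `interaction_network` from [induce_subnetwork()].
#' @param original_table the full-network `centrality_table` (used only for
#'   the original ranks); may be `NULL`.
#' @return a data.frame with columns `rank`, `name`, `degree`,
#'   `betweenness`, `original_rank`.
#' @export
rerank_subnetwork <- function(sub, original_table = NULL) {
  tab <- centrality_table(sub)
  ord <- order(-tab$degree, -tab$betweenness, tab$name, method = "radix")
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  if (!is.null(original_table)) {
    o <- order(-original_table$degree, original_table$name,
               method = "radix")
    orig_rank <- seq_len(nrow(original_table))
    names(orig_rank) <- original_table$name[o]
    tab$original_rank <- as.integer(orig_rank[tab$name])
  } else {
    tab$original_rank <- NA_integer_
  }
  rownames(tab) <- NULL
  tab[, c("rank", "name", "degree", "betweenness", "original_rank")]
}
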
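#' Run the full interactomic screening pipeline
#'
#' Executes read -> main-component extraction -> centrality -> power-law fit
#' -> hub/bottleneck/hub-bottleneck screening -> sub-network induction and
#' re-ranking -> (optionally) action-layer analysis, and writes the tables
#' and a JSON report to `out_dir`. A failed power-law fit (too few distinct
#' degrees) is downgraded to a warning because the screening does not depend
#' on it; every other stage error propagates, prefixed with the stage name.
#'
#' Outputs written when `out_dir` is given: `nodes_table.tsv` (per-node
#' degree/betweenness/flags), `subnetwork_table.tsv` (re-ranked central
#' genes), `action_summary.tsv` (per-layer participation, when actions are
#' supplied) and `report.json`. The report is self-describing: every number
#' is keyed by the rule and parameters that produced it, and identical
#' inputs and configuration yield byte-identical `report.json`.
#'
#' @param edges path to an edge-list file, or an `interaction_network`.
#' @param actions optional path to an action TSV, or an `action_graph`
#'   (its node set is intersected with the central genes if it was built on
#'   them already, otherwise it must cover them).
#' @param format edge-list format, passed to [read_edge_list()].
#' @param min_score optional confidence cutoff, passed to
#'   [read_edge_list()].
#' @param hub_rule,bottleneck_frac screening parameters, see [screen()].
#' @param out_dir optional output directory (created if missing).
#' @return a `pipeline_report` list: `input` (node/edge/isolated/main
#'   component counts), `power_law_fit` (or `NULL`), `screening`,
#'   `subnetwork` (re-ranked table), `actions` (layer summaries or `NULL`),
#'   and `parameters`.
#' @export
run_pipeline <- function(edges, actions = NULL,
                         format = c("plain", "string_tsv"),
                         min_score = NULL,
                         hub_rule = "mean_sd", bottleneck_frac = 0.05,
                         out_dir = NULL) {
  format <- match.arg(format)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  net <- if (inherits(edges, "interaction_network")) edges else
    stage("read", read_edge_list(edges, format = format,
                                 min_score = min_score))
  main <- stage("main_component", main_component(net))
  tab <- stage("centrality", centrality_table(main))
  fit <- tryCatch(fit_power_law(degree_distribution(tab)),
                  error = function(e) {
                    warning("power-law fit skipped: ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                  })
  scr <- stage("screening",
               screen(tab, hub_rule = hub_rule,
                      bottleneck_frac = bottleneck_frac))
  sub <- stage("subnetwork", induce_subnetwork(main, scr$central))
  sub_tab <- stage("subnetwork", rerank_subnetwork(sub, tab))

  act_summary <- NULL
  act_graph <- NULL
  if (!is.null(actions)) {
    act_graph <- stage("actions", {
      if (inherits(actions, "action_graph")) actions else {
        edges_df <- read_actions(actions)
        nodes <- sort(unique(c(scr$central, edges_df$source,
                               edges_df$target)))
        action_graph(nodes, edges_df)
      }
    })
    act_summary <- stage("actions", summarize_actions(act_graph))
  }

  report <- list(
    input = list(
      n_nodes = n_nodes(net),
      n_edges = n_edges(net),
      n_isolated = sum(node_degrees(net) == 0L),
      main_component_size = n_nodes(main),
      main_component_edges = n_edges(main)),
    power_law_fit = if (is.null(fit)) NULL else
      fit[c("a", "b", "correlation", "r_squared", "n_points")],
    screening = list(
      hub_rule = hub_rule,
      degree_threshold = scr$degree_threshold,
      bottleneck_rule = sprintf("top %.3f by betweenness, ceiling",
                                bottleneck_frac),
      bottleneck_count = scr$bottleneck_count,
      hubs = scr$hubs,
      bottlenecks = scr$bottlenecks,
      hub_bottlenecks = scr$hub_bottlenecks,
      n_central = length(scr$central)),
    subnetwork = sub_tab,
    actions = if (is.null(act_summary)) NULL else list(
      participation = lapply(act_summary$layers, function(l)
        list(count = l$count, percent = l$percent)),
      top_regulators = act_summary$top_regulators,
      inhibition_components = act_summary$inhibition_components,
      reciprocal_pairs = lapply(act_summary$layers,
                                function(l) l$reciprocal_pairs)),
    parameters = list(format = format, min_score = min_score,
                      hub_rule = hub_rule,
                      bottleneck_frac = bottleneck_frac))
  class(report) <- "pipeline_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_node_table(tab, file.path(out_dir, "nodes_table.tsv"),
                     screening = scr)
    utils::write.table(sub_tab, file.path(out_dir, "subnetwork_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(act_summary)) {
      part <- do.call(rbind, lapply(names(act_summary$layers), function(a) {
        l <- act_summary$layers[[a]]
        data.frame(action = a, participants = l$count,
                   percent = l$percent, stringsAsFactors = FALSE)
      }))
      utils::write.table(part, file.path(out_dir, "action_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "<pipeline_report: %d nodes (%d isolated), main component %d; %d hubs, %d bottlenecks, %d hub-bottlenecks>\n",
    x$input$n_nodes, x$input$n_isolated, x$input$main_component_size,
    length(x$screening$hubs), length(x$screening$bottlenecks),
    length(x$screening$hub_bottlenecks)))
  invisible(x)
}
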
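#' Read an undirected interaction edge list
#'
#' Two on-disk layouts are supported:
#' \describe{
#'   \item{`string_tsv`}{a STRING-style tab-separated export with a header
#'     line holding at least two node columns (`#node1`, `node2`) and
#'     optionally a `combined_score` column. Scores larger than 1 are taken
#'     to be on STRING's 0-1000 scale and divided by 1000.}
#'   \item{`plain`}{a headerless file with two whitespace- or tab-separated
#'     gene symbols per row.}
#' }
#' Duplicate rows and reversed duplicates collapse to a single undirected
#' edge. Self-loop rows are dropped with a warning; the dropped count is
#' attached as attribute `self_loops_dropped`.
#'
#' @param path file path.
#' @param format `"plain"` (default) or `"string_tsv"`.
#' @param min_score optional confidence cutoff in \[0, 1\]; edges scoring
#'   below it are discarded. No cutoff is applied by default.
#' @return a validated [interaction_network()].
#' @export
read_edge_list <- function(path, format = c("plain", "string_tsv"),
                           min_score = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)

  score <- NULL
  if (format == "string_tsv") {
    header <- strsplit(sub("^#", "", lines[[1L]]), "\t", fixed = TRUE)[[1L]]
    header <- trimws(header)
    if (length(header) < 2L) {
      stop("malformed header in ", path, ": need at least two node columns")
    }
    score_col <- match("combined_score", header)
    body <- lines[-1L]
    if (length(body) == 0L) stop("no data rows in ", path)
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != length(header))
    if (length(bad)) {
      stop(sprintf("malformed row at line %d of %s: expected %d columns, got %d",
                   bad[1L] + 1L, path, length(header),
                   lengths(parts)[bad[1L]]))
    }
    m <- do.call(rbind, parts)
    ends <- m[, 1:2, drop = FALSE]
    if (!is.na(score_col)) {
      score <- suppressWarnings(as.numeric(m[, score_col]))
      if (anyNA(score)) {
        stop(sprintf("non-numeric combined_score at line %d of %s",
                     which(is.na(score))[1L] + 1L, path))
      }
      if (any(score > 1)) score <- score / 1000
    }
  } else {
    parts <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) {
      stop(sprintf("malformed row at line %d of %s: expected 2 columns, got %d",
                   bad[1L], path, lengths(parts)[bad[1L]]))
    }
    ends <- do.call(rbind, parts)
  }

  loop <- ends[, 1L] == ends[, 2L]
  n_loops <- sum(loop)
  if (n_loops > 0L) {
    warning(sprintf("dropped %d self-loop row(s) from %s", n_loops, path))
    ends <- ends[!loop, , drop = FALSE]
    if (!is.null(score)) score <- score[!loop]
  }
  if (!is.null(score) && !is.null(min_score)) {
    keep <- score >= min_score
    ends <- ends[keep, , drop = FALSE]
    score <- score[keep]
  }
  nodes <- sort(unique(c(ends)))
  # companion node list written by write_edge_list() carries isolated genes
  nodes_file <- paste0(path, ".nodes")
  if (file.exists(nodes_file)) {
    nodes <- sort(unique(c(nodes, readLines(nodes_file, warn = FALSE))))
  }
  if (length(nodes) == 0L) stop("no usable edges in ", path)
  net <- interaction_network(nodes, ends, score = score,
                             name = basename(path))
  attr(net, "self_loops_dropped") <- n_loops
  net
}

#' Write an interaction network as a plain two-column edge list
#'
#' Isolated nodes cannot be represented in a bare edge list, so they are
#' written as a companion `<path>.nodes` file (one symbol per line) when
#' present; [read_edge_list()] followed by re-adding that file's nodes
#' round-trips any network. Networks without isolated nodes round-trip from
#' the edge list alone.
#'
#' @param net an `interaction_network`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  writeLines(paste(net$edges[, 1L], net$edges[, 2L], sep = "\t"), path)
  iso <- net$nodes[node_degrees(net) == 0L]
  if (length(iso)) writeLines(iso, paste0(path, ".nodes"))
  invisible(path)
}

.ACTIONS <- c("expression", "activation", "inhibition")
.SIGNS <- c("up", "down", "none")

#' Read a typed, signed action edge list
#'
#' Expects a tab-separated file with header columns `source`, `target`,
#' `action`, `sign`. `action` must be one of `expression`, `activation`,
#' `inhibition`; `sign` one of `up`, `down`, `none`, and may differ from
#' `none` only on `expression` edges (the drawn regulatory direction of an
#' expression arrow). Self-edges and duplicated
#' (source, target, action, sign) quadruples are rejected.
#'
#' @param path file path.
#' @return a data.frame with columns `source`, `target`, `action`, `sign`.
#' @export
read_actions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "",
                          quote = "")
  need <- c("source", "target", "action", "sign")
  if (!all(need %in% names(df))) {
    stop("action file must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  validate_action_edges(df)
  df
}

validate_action_edges <- function(df) {
  bad_action <- setdiff(unique(df$action), .ACTIONS)
  if (length(bad_action)) {
    stop("unknown action type: ", paste(bad_action, collapse = ", "))
  }
  bad_sign <- setdiff(unique(df$sign), .SIGNS)
  if (length(bad_sign)) {
    stop("unknown sign: ", paste(bad_sign, collapse = ", "))
  }
  offending <- df$action != "expression" & df$sign != "none"
  if (any(offending)) {
    stop("sign given for non-expression action on edge ",
         df$source[offending][1L], " -> ", df$target[offending][1L])
  }
  if (any(df$source == df$target)) stop("self-edges are not allowed")
  key <- do.call(paste, c(df, sep = "\r"))
  if (anyDuplicated(key)) stop("duplicate action edge rows")
  invisible(df)
}

#' Write an action edge list
#' @param edges data.frame as returned by [read_actions()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_actions <- function(edges, path) {
  validate_action_edges(edges)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the node attribute table
#'
#' Emits a TSV with columns `name`, `degree`, `betweenness`, `is_hub`,
#' `is_bottleneck`, `is_hub_bottleneck`, sorted by degree descending then
#' name ascending, betweenness printed with 6 decimal places. When a
#' screening result is supplied the three flag columns are filled from it;
#' otherwise all flags are FALSE.
#'
#' @param table a centrality table (see [centrality_table()]).
#' @param path output file path.
#' @param screening optional `screening_result` for the flag columns.
#' @return invisibly, the data.frame that was written.
#' @export
write_node_table <- function(table, path, screening = NULL) {
  if (nrow(table) == 0L) stop("empty table")
  ord <- order(-table$degree, table$name, method = "radix")
  out <- table[ord, c("name", "degree", "betweenness")]
  out$is_hub <- out$name %in% (if (is.null(screening)) character(0)
                               else screening$hubs)
  out$is_bottleneck <- out$name %in% (if (is.null(screening)) character(0)
                                      else screening$bottlenecks)
  out$is_hub_bottleneck <- out$is_hub & out$is_bottleneck
  out$betweenness <- sprintf("%.6f", out$betweenness)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
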
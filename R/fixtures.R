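#' Published migraine central-gene tables
#'
#' The 33-gene central table of the migraine PPI screening (degree and
#' betweenness computed over the 383-node main component of the STRING
#' network), and the matching sub-network table with degree and betweenness
#' recomputed within the 33-gene induced sub-network plus each gene's row
#' position (`original_rank`) in the full-network table. Values are
#' transcribed verbatim from the published tables; note the published
#' sub-network table carries `original_rank = 29` for both MMP9 and CACNA1A
#' (an apparent misprint for MMP9, whose full-table row is 22) and this
#' transcription preserves it.
#'
#' These tables serve as a candidate pool for screening arithmetic: applying
#' the top-20-by-degree and top-20-by-betweenness rules to the 33 rows
#' reproduces the published 7 hub-bottlenecks.
#'
#' @return `table1_fixture()`: a `centrality_table` with 33 rows, `n`
#'   attribute 383 (the network the statistics were computed over).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "migraine_central_table1.tsv",
                      package = "ppiscreen", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$degree <- as.integer(tab$degree)
  attr(tab, "n") <- 383L
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' @rdname table1_fixture
#' @return `table2_fixture()`: data.frame with columns `name`, `degree`,
#'   `betweenness`, `original_rank` (33 rows).
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "migraine_central_table2_subnetwork.tsv",
                      package = "ppiscreen", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$degree <- as.integer(tab$degree)
  tab$original_rank <- as.integer(tab$original_rank)
  tab
}

#' Synthetic action graph encoding the published regulatory facts
#'
#' The published action maps are figures, not edge lists, so their exact
#' edges are unrecoverable; this synthetic stand-in plants every regulatory
#' fact the accompanying text states and fills the remaining structure with
#' fixed filler edges chosen once:
#' \itemize{
#' \item expression layer: 23 of the 33 genes participate (70%); GNB3 is
#'   isolated there (the only hub-bottleneck that is); INS sends 6 up- and 4
#'   down-edges with 2 targets receiving both, regulating 8 unique genes;
#'   CREB1 regulates 5 genes; TNF regulates 7 genes and receives none;
#'   ALB's single expression edge is the up-regulation it receives from INS.
#' \item activation layer: 27 genes participate, including all 7
#'   hub-bottlenecks; FOS, IL6 and MMP9 receive the most arrows.
#' \item inhibition layer: 11 genes (33%) in three separate weak components
#'   (KNG1-NOS3; the calcium-channel subunits with GNB3 and INS, where GNB3
#'   inhibits INS only indirectly; NOTCH1-FOS-TH-CREB1), 9 of them
#'   inhibitors, with reciprocal inhibition between FOS and CREB1.
#' }
#'
#' @return an [action_graph()] over the 33 central genes.
#' @export
paper_action_fixture <- function() {
  central <- table1_fixture()$name
  e <- function(source, target, action, sign = "none") {
    data.frame(source = source, target = target, action = action,
               sign = sign, stringsAsFactors = FALSE)
  }
  expr <- rbind(
    e("INS", c("ALB", "FOS", "BDNF", "POMC", "NPY", "SST"),
      "expression", "up"),
    e("INS", c("NPY", "SST", "CRH", "TAC1"), "expression", "down"),
    e("CREB1", c("FOS", "BDNF", "TH"), "expression", "up"),
    e("CREB1", c("NTS", "EDN1"), "expression", "down"),
    e("TNF", c("IL6", "MMP9", "NOS3", "FOS"), "expression", "up"),
    e("TNF", c("EDN1", "EGF", "F2"), "expression", "down"),
    e("NPS", "KNG1", "expression", "up"),
    e("HTR7", "PRL", "expression", "down"))
  activ <- rbind(
    e(c("CREB1", "BDNF", "TH", "EGF"), "FOS", "activation"),
    e(c("TNF", "INS", "F2"), "IL6", "activation"),
    e(c("EGF", "TNF", "IL6"), "MMP9", "activation"),
    e("FOS", "BDNF", "activation"),
    e("INS", "ALB", "activation"),
    e(c("NPS", "CRH"), "POMC", "activation"),
    e("KNG1", "F2", "activation"),
    e(c("NTS", "CACNA1A"), "TAC1", "activation"),
    e(c("GNB3", "SST"), "INS", "activation"),
    e(c("EDN1", "CACNA1C"), "NOS3", "activation"),
    e("HTR7", "CREB1", "activation"),
    e("NPY", "CRH", "activation"),
    e("PRL", "EDN1", "activation"),
    e("NOTCH1", "TH", "activation"))
  inhib <- rbind(
    e("KNG1", "NOS3", "inhibition"),
    e("GNB3", "CACNA1C", "inhibition"),
    e(c("CACNA1C", "CACNA1A", "CACNA1B"), "INS", "inhibition"),
    e(c("NOTCH1", "CREB1", "TH"), "FOS", "inhibition"),
    e("FOS", "CREB1", "inhibition"))
  action_graph(central, rbind(expr, activ, inhib))
}

#' @rdname table1_fixture
#' @return `paper_fixture()`: list with elements `table1`, `table2`, and
#'   `actions` (see [paper_action_fixture()]).
#' @export
paper_fixture <- function() {
  list(table1 = table1_fixture(),
       table2 = table2_fixture(),
       actions = paper_action_fixture())
}
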
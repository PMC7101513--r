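toy_graph <- function() {
  action_graph(LETTERS[1:6], data.frame(
    source = c("A", "A", "B", "C", "C", "E"),
    target = c("B", "C", "C", "A", "D", "D"),
    action = c("expression", "expression", "activation", "activation",
               "inhibition", "inhibition"),
    sign = c("up", "down", "none", "none", "none", "none"),
    stringsAsFactors = FALSE))
}

test_that("layers partition the edge set and keep the full node list", {
  g <- toy_graph()
  layers <- lapply(c("expression", "activation", "inhibition"),
                   function(a) action_layer(g, a))
  expect_equal(sum(vapply(layers, function(l) nrow(l$edges), numeric(1))),
               nrow(g$edges))
  for (l in layers) expect_identical(l$nodes, g$nodes)
  expect_error(action_layer(g, "binding"), "unknown action")

  empty <- action_graph(LETTERS[1:3])
  expect_equal(nrow(action_layer(empty, "expression")$edges), 0L)
  expect_equal(inhibition_components(empty), list())
})

test_that("participation counts non-isolated genes and rounds to integer percent", {
  g <- toy_graph()
  p <- participation(g, "expression")
  expect_setequal(p$participants, c("A", "B", "C"))
  expect_equal(p$count, 3L)
  expect_equal(p$percent, 50L)  # 3 of 6
  expect_equal(participation(g, "inhibition")$percent, 50L)
  expect_error(participation(action_graph(character(0)), "expression"),
               "no nodes")
})

test_that("published participation arithmetic holds on the planted fixture", {
  ag <- paper_action_fixture()
  pe <- participation(ag, "expression")
  expect_equal(pe$count, 23L)
  expect_equal(pe$percent, 70L)
  expect_false("GNB3" %in% pe$participants)
  hb <- c("ALB", "INS", "NPS", "GNB3", "BDNF", "EGF", "NTS")
  expect_equal(sum(hb %in% pe$participants), 6L)

  pa <- participation(ag, "activation")
  expect_equal(pa$count, 27L)
  expect_true(all(hb %in% pa$participants))

  pi <- participation(ag, "inhibition")
  expect_equal(pi$count, 11L)
  expect_equal(pi$percent, 33L)
  inhibitors <- unique(action_layer(ag, "inhibition")$edges$source)
  expect_length(inhibitors, 9L)
})

test_that("regulatory tallies count signed out-edges with target deduplication", {
  ag <- paper_action_fixture()
  ins <- regulatory_tally(ag, "INS")
  expect_equal(ins$up_out, 6L)
  expect_equal(ins$down_out, 4L)
  expect_equal(ins$unique_targets, 8L)
  expect_equal(regulatory_tally(ag, "CREB1")$unique_targets, 5L)
  tnf <- regulatory_tally(ag, "TNF")
  expect_equal(tnf$unique_targets, 7L)
  expect_equal(tnf$in_degree, 0L)
  # ALB only receives the single INS edge
  alb <- regulatory_tally(ag, "ALB")
  expect_equal(alb$unique_targets, 0L)
  expect_equal(alb$in_degree, 1L)
  expect_true(alb$participates)
  # isolated gene: zero tally, no participation
  gnb3 <- regulatory_tally(ag, "GNB3")
  expect_false(gnb3$participates)
  expect_error(regulatory_tally(ag, "NOPE"), "unknown gene")

  both <- action_graph(c("X", "Y"), data.frame(
    source = "X", target = "Y", action = "expression",
    sign = c("up", "down"), stringsAsFactors = FALSE))
  t <- regulatory_tally(both, "X")
  expect_equal(c(t$up_out, t$down_out, t$unique_targets), c(1L, 1L, 1L))
})

test_that("tally dedup bounds hold on random action graphs", {
  net <- generate_paper_like_network(
    generator_config(n_total = 40, n_isolated = 0, seed = 6))
  for (seed in 1:10) {
    ag <- annotate_actions(net, net$nodes[1:20], action_config(
      n_expression = 30, n_activation = 10, n_inhibition = 5), seed = seed)
    for (gene in ag$nodes) {
      t <- regulatory_tally(ag, gene)
      expect_lte(t$unique_targets, t$up_out + t$down_out)
      expect_gte(t$unique_targets, max(t$up_out, t$down_out))
    }
  }
})

test_that("participation is invariant under edge direction reversal", {
  ag <- paper_action_fixture()
  rev <- action_graph(ag$nodes, transform(ag$edges, source = target,
                                          target = source))
  for (a in c("expression", "activation", "inhibition")) {
    expect_equal(participation(rev, a)$count, participation(ag, a)$count)
  }
})

test_that("inhibition splits into the three published parts", {
  parts <- inhibition_components(paper_action_fixture())
  expect_length(parts, 3L)
  expect_equal(parts[[1]], c("CACNA1A", "CACNA1B", "CACNA1C", "GNB3",
                             "INS"))
  expect_equal(parts[[2]], c("CREB1", "FOS", "NOTCH1", "TH"))
  expect_equal(parts[[3]], c("KNG1", "NOS3"))

  two <- action_graph(LETTERS[1:4], data.frame(
    source = c("A", "C"), target = c("B", "D"), action = "inhibition",
    sign = "none", stringsAsFactors = FALSE))
  expect_equal(inhibition_components(two), list(c("A", "B"), c("C", "D")))
})

test_that("reciprocal pairs require both directions within one layer", {
  ab <- action_graph(c("A", "B"), data.frame(
    source = c("A", "B"), target = c("B", "A"), action = "inhibition",
    sign = "none", stringsAsFactors = FALSE))
  expect_equal(reciprocal_pairs(ab, "inhibition"),
               data.frame(gene1 = "A", gene2 = "B",
                          stringsAsFactors = FALSE))
  one <- action_graph(c("A", "B"), data.frame(
    source = "A", target = "B", action = "inhibition", sign = "none",
    stringsAsFactors = FALSE))
  expect_equal(nrow(reciprocal_pairs(one, "inhibition")), 0L)

  rp <- reciprocal_pairs(paper_action_fixture(), "inhibition")
  expect_equal(rp, data.frame(gene1 = "CREB1", gene2 = "FOS",
                              stringsAsFactors = FALSE))
})
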
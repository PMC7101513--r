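test_that("mean+SD hub rule uses strict inequality and population SD", {
  # degrees [10,1,1,1,1]: mean 2.8, population SD 3.6, threshold 6.4
  tab <- data.frame(name = c("H", "a", "b", "c", "d"),
                    degree = c(10L, 1L, 1L, 1L, 1L),
                    betweenness = c(1, 0, 0, 0, 0))
  hubs <- select_hubs(tab)
  expect_equal(as.character(hubs), "H")
  expect_equal(attr(hubs, "threshold"), 6.4, tolerance = 1e-12)

  # all degrees equal (a cycle): SD 0, nothing strictly exceeds the mean
  cyc <- data.frame(name = LETTERS[1:5], degree = 2L, betweenness = 0.1)
  expect_length(select_hubs(cyc), 0L)
  expect_length(select_hubs(cyc, strict = FALSE), 5L)
  expect_error(select_hubs(cyc[0, ]), "empty")
})

test_that("bottleneck count is ceiling(frac * n) with pinned tie-breaks", {
  mk <- function(n) data.frame(name = sprintf("g%03d", 1:n), degree = 1L,
                               betweenness = seq(1, 0, length.out = n))
  expect_equal(attr(select_bottlenecks(mk(383)), "count"), 20)
  expect_equal(attr(select_bottlenecks(mk(20)), "count"), 1)
  expect_equal(as.character(select_bottlenecks(mk(20))), "g001")

  # boundary tie resolved by degree descending then name ascending
  tie <- data.frame(name = c("A", "Zed", "Bee", "C"),
                    degree = c(5L, 2L, 3L, 1L),
                    betweenness = c(0.9, 0.5, 0.5, 0.1))
  got <- select_bottlenecks(tie, k = 2)
  expect_equal(as.character(got), c("A", "Bee"))
  got3 <- select_bottlenecks(tie, k = 3)
  expect_equal(as.character(got3), c("A", "Bee", "Zed"))
})

test_that("screening the printed 33-gene pool reproduces the published sets", {
  tab <- table1_fixture()
  res <- screen(tab, hub_rule = "top_k", hub_k = 20, bottleneck_k = 20)
  expect_setequal(res$hub_bottlenecks,
                  c("ALB", "INS", "NPS", "GNB3", "BDNF", "EGF", "NTS"))
  expect_length(res$hubs, 20)
  expect_length(res$bottlenecks, 20)
  expect_length(res$central, 33)
  expect_equal(length(res$central),
               length(res$hubs) + length(res$bottlenecks) -
                 length(res$hub_bottlenecks))
})

test_that("screening result invariants hold on random centrality tables", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    tab <- data.frame(name = sprintf("g%02d", 1:n),
                      degree = as.integer(stats::rpois(n, 4)),
                      betweenness = stats::runif(n))
    res <- screen(tab)
    expect_setequal(res$hub_bottlenecks,
                    intersect(res$hubs, res$bottlenecks))
    expect_equal(length(res$central),
                 length(res$hubs) + length(res$bottlenecks) -
                   length(res$hub_bottlenecks))
    expect_true(all(tab$degree[match(res$hubs, tab$name)] >
                      res$degree_threshold))
    expect_equal(length(res$bottlenecks), ceiling(0.05 * n))
    # bottlenecks are exactly the top-count by betweenness (up to ties)
    kth <- sort(tab$betweenness, decreasing = TRUE)[res$bottleneck_count]
    expect_true(all(tab$betweenness[match(res$bottlenecks, tab$name)] >=
                      kth))
  }
})

test_that("screening is deterministic: same table, byte-identical serialization", {
  tab <- table1_fixture()
  r1 <- screen(tab, hub_rule = "top_k", hub_k = 20, bottleneck_k = 20)
  r2 <- screen(tab[sample(nrow(tab)), ], hub_rule = "top_k", hub_k = 20,
               bottleneck_k = 20)
  expect_identical(jsonlite::toJSON(unclass(r1)),
                   jsonlite::toJSON(unclass(r2)))
})

test_that("induced subnetworks keep exactly the central nodes and their edges", {
  tri <- triangle_net()
  sub <- induce_subnetwork(tri, c("A", "B"))
  expect_setequal(sub$nodes, c("A", "B"))
  expect_equal(n_edges(sub), 1L)
  all_sub <- induce_subnetwork(tri, c("A", "B", "C"))
  expect_identical(all_sub$edges, tri$edges)
  expect_error(induce_subnetwork(tri, c("A", "X")), "X")

  net <- generate_paper_like_network(
    generator_config(n_total = 100, n_isolated = 10, seed = 2))
  central <- sample(net$nodes, 30)
  sub2 <- induce_subnetwork(net, central)
  brute <- sum(net$edges[, 1] %in% central & net$edges[, 2] %in% central)
  expect_equal(n_edges(sub2), brute)
})

test_that("sub-network re-ranking recomputes centrality and keeps original ranks", {
  net <- main_component(generate_paper_like_network(
    generator_config(n_total = 120, n_isolated = 0, seed = 31)))
  tab <- centrality_table(net)
  res <- screen(tab)
  sub <- induce_subnetwork(net, res$central)
  rr <- rerank_subnetwork(sub, tab)

  # subgraph degrees never exceed full-network degrees, nor |central|-1
  full_deg <- tab$degree[match(rr$name, tab$name)]
  expect_true(all(rr$degree <= full_deg))
  expect_true(all(rr$degree <= length(res$central) - 1L))

  # ranking matches a brute-force sort of the recomputed table
  sub_tab <- centrality_table(sub)
  ord <- order(-sub_tab$degree, -sub_tab$betweenness, sub_tab$name)
  expect_equal(rr$name, sub_tab$name[ord])
  expect_equal(rr$rank, seq_len(nrow(rr)))

  # original_rank points back into the degree-sorted full table
  full_sorted <- tab$name[order(-tab$degree, tab$name)]
  expect_equal(rr$original_rank, match(rr$name, full_sorted))
})

test_that("planted high-degree hubs are recovered by the mean+SD rule", {
  for (seed in 1:20) {
    cfg <- generator_config(n_total = 150, n_isolated = 10, seed = seed,
                            n_planted_hubs = 3, planted_hub_degree = 60)
    net <- generate_paper_like_network(cfg)
    planted <- attr(net, "planted_hubs")
    main <- main_component(net)
    deg <- node_degrees(main)
    # planting precondition: degree at least mean + 3 SD of the component
    thr3 <- mean(deg) + 3 * sqrt(mean((deg - mean(deg))^2))
    expect_true(all(deg[planted] >= thr3))
    hubs <- select_hubs(data.frame(name = names(deg),
                                   degree = as.integer(deg),
                                   betweenness = 0))
    expect_true(all(planted %in% hubs),
                info = sprintf("seed %d", seed))
  }
})
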
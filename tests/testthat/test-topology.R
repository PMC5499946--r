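test_that("node betweenness matches closed forms", {
  # star: all pairs of leaves route through the center
  for (m in c(2, 3, 6)) {
    star <- cg(data.frame(from = 1, to = 2:(m + 1)))
    bc <- node_betweenness(star)
    expect_equal(bc[1], 1)
    expect_equal(bc[-1], rep(0, m))
  }
  # path P4: node 2 carries pairs (1,3), (1,4) -> 2 * 2/((4-1)(4-2))
  p4 <- toy_graph_path(4)
  expect_equal(node_betweenness(p4), c(0, 2 / 3, 2 / 3, 0))
  # cycle C4: each node carries half of one opposite pair
  c4 <- cg(data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1)))
  expect_equal(node_betweenness(c4), rep(1 / 6, 4))
  expect_error(node_betweenness(cg(data.frame(from = 1, to = 2))),
               "N >= 3")
})

test_that("edge betweenness matches closed forms", {
  single <- cg(data.frame(from = 1, to = 2))
  expect_equal(edge_betweenness(single), 1)
  p3 <- toy_graph_path(3)
  expect_equal(edge_betweenness(p3), c(2 / 3, 2 / 3))
  star3 <- cg(data.frame(from = 1, to = 2:4))
  expect_equal(edge_betweenness(star3), rep(0.5, 3))
})

test_that("betweenness equals the brute-force path-enumeration oracle", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    g <- random_connected_graph(n)
    bf <- bf_betweenness(g)
    expect_equal(node_betweenness(g), bf$node * 2 / ((n - 1) * (n - 2)),
                 tolerance = 1e-12)
    expect_equal(edge_betweenness(g), bf$edge * 2 / (n * (n - 1)),
                 tolerance = 1e-12)
  }
})

test_that("weighted betweenness prefers large interfaces and matches its oracle", {
  # two routes a-b-c (areas 10) and a-d-c (areas 1): the large-interface
  # route is 'shorter' (1/10 + 1/10 < 1 + 1)
  sq <- cg(data.frame(from = c(1, 2, 1, 4), to = c(2, 3, 4, 3)),
           areas = c(10, 10, 1, 1))
  wbc <- weighted_node_betweenness(sq)
  expect_gt(wbc[2], 0)
  expect_equal(wbc[4], 0)

  # uniform areas: identical to unweighted
  set.seed(11)
  for (rep in 1:5) {
    g <- random_connected_graph(sample(5:15, 1))
    expect_equal(weighted_node_betweenness(g), node_betweenness(g),
                 tolerance = 1e-12)
  }
  # random areas: equals the Dijkstra-enumeration oracle
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    g <- random_connected_graph(n, areas = TRUE)
    bf <- bf_betweenness(g, weighted = TRUE)
    expect_equal(weighted_node_betweenness(g),
                 bf$node * 2 / ((n - 1) * (n - 2)), tolerance = 1e-9)
  }
  bad <- cg(data.frame(from = 1, to = 2), n = 3)
  bad$edges$area_um2 <- 0
  expect_error(weighted_node_betweenness(bad), "> 0")
})

test_that("current-flow edge betweenness behaves like current in a resistor network", {
  single <- cg(data.frame(from = 1, to = 2))
  expect_equal(current_flow_edge_betweenness(single), 1)
  p3 <- toy_graph_path(3)
  rw <- current_flow_edge_betweenness(p3)
  expect_equal(rw[1], rw[2])
  # on trees all flow follows the unique path: equals shortest-path ebc
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    g <- random_connected_graph(n, extra = 0)
    expect_equal(current_flow_edge_betweenness(g), edge_betweenness(g),
                 tolerance = 1e-9)
  }
  # cycle: flow splits 1:2 on the two routes of C3? every edge symmetric
  c3 <- cg(data.frame(from = c(1, 2, 1), to = c(2, 3, 3)))
  rw3 <- current_flow_edge_betweenness(c3)
  expect_equal(rw3, rep(rw3[1], 3))
})

test_that("disconnected graphs are computed per component with a warning", {
  g <- cg(data.frame(from = c(1, 3), to = c(2, 4)), n = 4)
  expect_warning(rw <- current_flow_edge_betweenness(g), "disconnected")
  expect_equal(rw, rep(2 / (4 * 3), 2))
  expect_warning(measure_topology(g, "bc"), "disconnected")
})

test_that("log10 transform excludes zeros and reports the count", {
  out <- log10_transform(c(0, 0.01, 0.1))
  expect_equal(out$values, c(-2, -1))
  expect_equal(out$n_excluded, 1)
  expect_equal(log10_transform(1)$values, 0)
  expect_equal(log10_transform(0.001)$values, -3)
  expect_error(log10_transform(-1), ">= 0")
})

test_that("reporting masks rows without touching values", {
  g <- generate_organ(toy_organ_spec(seed = 1))
  g <- mark_buffer(g, 2)
  mt <- measure_topology(g)
  rep_tab <- report_central(mt$nodes)
  expect_false(any(rep_tab$buffer))
  expect_false(any(rep_tab$cell_type == "vasculature"))
  m <- match(rep_tab$cell_id, mt$nodes$cell_id)
  expect_identical(rep_tab$bc, mt$nodes$bc[m])

  # buffering by masking differs from buffering by deletion: recomputing
  # on the trimmed graph changes the retained cells' values
  keep <- !g$nodes$buffer
  sub <- cell_graph(g$nodes[keep, ],
                    g$edges[g$edges$from %in% g$nodes$cell_id[keep] &
                              g$edges$to %in% g$nodes$cell_id[keep], ])
  bc_del <- suppressWarnings(node_betweenness(sub))
  m2 <- match(sub$nodes$cell_id, mt$nodes$cell_id)
  expect_gt(max(abs(bc_del - mt$nodes$bc[m2])), 1e-6)

  all_buf <- mt$nodes
  all_buf$buffer <- TRUE
  expect_warning(out <- report_central(all_buf), "all cells")
  expect_equal(nrow(out), 0)
})

test_that("measure_topology assembles the requested measures", {
  g <- generate_organ(toy_organ_spec(seed = 9))
  mt <- measure_topology(g)
  expect_true(all(c("degree", "bc", "wbc", "log10_bc") %in%
                    names(mt$nodes)))
  expect_true("ebc" %in% names(mt$edges))
  expect_equal(mt$nodes$degree,
               unname(as.integer(igraph::degree(as_igraph(g)))))
  expect_true(all(mt$nodes$bc >= 0 & mt$nodes$bc <= 1))
  expect_true(all(mt$edges$ebc >= 0 & mt$edges$ebc <= 1))
  expect_equal(mt$nodes$log10_bc[mt$nodes$bc > 0],
               log10(mt$nodes$bc[mt$nodes$bc > 0]))
})
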
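test_that("degree, betweenness and closeness match definitions and oracles", {
  k4 <- complete_net(letters[1:4])
  expect_equal(as.numeric(dc_scores(k4)), rep(3, 4))
  p3 <- path_net(c("a", "b", "c"))
  expect_equal(as.numeric(bc_scores(p3)[c("a", "b", "c")]), c(0, 1, 0))
  expect_equal(as.numeric(cc_scores(p3)["a"]), 2 / 3)
  s4 <- star_net("h", c("x", "y", "z"))
  expect_equal(as.numeric(cc_scores(s4)["h"]), 1)

  for (seed in 1:15) {
    net <- er_net(8, 0.3, seed = 400 + seed)
    a <- adjacency_of(net)
    nms <- rownames(a)
    expect_equal(as.numeric(bc_scores(net)[nms]), oracle_bc(a), tolerance = 1e-10)
    expect_equal(as.numeric(cc_scores(net)[nms]), oracle_cc(a), tolerance = 1e-10)
    expect_equal(as.numeric(dc_scores(net)[nms]), as.numeric(rowSums(a)))
  }
})

test_that("subgraph centrality matches eigen form and truncated series", {
  k2 <- quiet_net(edge_df("a", "b"))
  expect_equal(as.numeric(sc_scores(k2)), rep(cosh(1), 2), tolerance = 1e-10)
  iso <- quiet_net(edge_df("a", "b"), nodes = "z")
  expect_equal(as.numeric(sc_scores(iso)["z"]), 1, tolerance = 1e-10)
  for (seed in 1:10) {
    net <- er_net(10, 0.3, seed = 500 + seed)
    a <- adjacency_of(net)
    expect_equal(as.numeric(sc_scores(net)[rownames(a)]), oracle_sc_series(a),
                 tolerance = 1e-6)
  }
})

test_that("eigenvector centrality solves Av = lambda v at unit norm", {
  c5 <- cycle_net(letters[1:5])
  ev <- ec_scores(c5)
  expect_equal(as.numeric(ev), rep(ev[[1]], 5), tolerance = 1e-10)  # symmetry
  k2 <- quiet_net(edge_df("a", "b"))
  expect_equal(as.numeric(ec_scores(k2)), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  net <- er_net(30, 0.15, seed = 600)
  a <- adjacency_of(net)
  v <- as.numeric(ec_scores(net)[rownames(a)])
  lam <- max(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(sum(v^2), 1, tolerance = 1e-10)
  expect_lt(max(abs(a %*% v - lam * v)), 1e-8)
})

test_that("information centrality is symmetric and tracks closeness on trees", {
  c4 <- cycle_net(letters[1:4])
  expect_equal(as.numeric(ic_scores(c4)), rep(ic_scores(c4)[[1]], 4),
               tolerance = 1e-10)
  k2 <- quiet_net(edge_df("a", "b"))
  expect_equal(ic_scores(k2)[["a"]], ic_scores(k2)[["b"]])
  iso <- quiet_net(edge_df("a", "b"), nodes = "z")
  expect_equal(as.numeric(ic_scores(iso)["z"]), 0)
  # on trees effective resistance equals path length, so IC and CC agree in
  # rank (IC values are rounded to restore ties lost to solve() float noise)
  for (seed in 1:10) {
    tr <- random_tree_net(7, seed = 700 + seed)
    nms <- igraph::V(tr)$name
    expect_equal(rank(round(as.numeric(ic_scores(tr)[nms]), 9)),
                 rank(round(as.numeric(cc_scores(tr)[nms]), 9)))
  }
})

test_that("bottleneck centrality counts deterministic BFS-tree bottlenecks", {
  p5 <- path_net(c("a", "b", "c", "d", "e"))
  bn <- bn_scores(p5)
  # rooted at an end, the middle node holds 3 of 5 descendants (> 5/4)
  expect_gte(bn[["c"]], 2)
  k2 <- quiet_net(edge_df("a", "b"))
  expect_equal(bn_scores(k2)[["a"]], bn_scores(k2)[["b"]])
  expect_identical(bn_scores(p5), bn_scores(p5))  # deterministic tie rule
  for (seed in 1:15) {
    net <- er_net(8, 0.3, seed = 800 + seed)
    a <- adjacency_of(net)
    expect_equal(as.numeric(bn_scores(net)[rownames(a)]),
                 as.numeric(oracle_bn(a, rownames(a))[rownames(a)]))
  }
})

test_that("DMNC scores the densest neighborhood component", {
  tri <- complete_net(c("a", "b", "c"))
  expect_equal(as.numeric(dmnc_scores(tri)["a"]), 1 / 2^1.7)
  star <- star_net("h", c("x", "y", "z"))
  expect_equal(as.numeric(dmnc_scores(star)["h"]), 0)  # neighbors disconnected
  k4 <- complete_net(letters[1:4])
  expect_equal(as.numeric(dmnc_scores(k4)["a"]), 3 / 3^1.7)
})

test_that("LAC and the lobby index read the local neighborhood", {
  star <- star_net("h", c("x", "y", "z", "w"))
  expect_equal(as.numeric(lac_scores(star)["h"]), 0)
  expect_equal(as.numeric(li_scores(star)["h"]), 1)  # leaves have degree 1
  k4 <- complete_net(letters[1:4])
  expect_equal(as.numeric(lac_scores(k4)["a"]), 2)   # neighborhood is K3
  expect_equal(as.numeric(li_scores(k4)["a"]), 3)
  tri <- complete_net(c("a", "b", "c"))
  expect_equal(as.numeric(lac_scores(tri)["a"]), 1)
  net <- er_net(25, 0.2, seed = 901)
  expect_true(all(li_scores(net) <= ppi_degree(net)[names(li_scores(net))]))
})

test_that("LeaderRank conserves total score and respects symmetry", {
  c5 <- cycle_net(letters[1:5])
  lr <- lr_scores(c5)
  expect_equal(as.numeric(lr), rep(1, 5), tolerance = 1e-8)
  net <- er_net(30, 0.15, seed = 950)
  lr2 <- lr_scores(net)
  expect_equal(sum(lr2), 30, tolerance = 1e-6)
  # stationarity: recomputing from the fixed point moves nothing
  expect_equal(lr_scores(net, tol = 1e-12), lr2, tolerance = 1e-7)
})

test_that("alpha-centrality matches the truncated Katz series", {
  c6 <- cycle_net(letters[1:6])
  expect_equal(as.numeric(nc_scores(c6)), rep(1 / 6, 6), tolerance = 1e-10)
  expect_equal(as.numeric(nc_scores(c6, alpha = 0)), rep(1 / 6, 6))
  for (seed in 1:8) {
    net <- er_net(10, 0.3, seed = 1000 + seed)
    a <- adjacency_of(net)
    lam <- max(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
    if (lam == 0) next
    alpha <- 0.9 / lam
    expect_equal(as.numeric(nc_scores(net)[rownames(a)]),
                 oracle_nc_series(a, alpha), tolerance = 1e-6)
  }
  net <- er_net(10, 0.3, seed = 1001)
  lam <- max(eigen(adjacency_of(net), symmetric = TRUE, only.values = TRUE)$values)
  expect_error(nc_scores(net, alpha = 1.1 / lam), "alpha")
})

test_that("measures are invariant under node relabeling", {
  net <- er_net(40, 0.12, seed = 1100)
  nms <- igraph::V(net)$name
  set.seed(1)
  relabel <- stats::setNames(sprintf("q%02d", sample(40)), nms)
  ed <- ppi_edges(net)
  net2 <- quiet_net(edge_df(relabel[ed$u], relabel[ed$v]),
                    nodes = unname(relabel))
  expr <- matrix(rnorm(40 * 12), nrow = 40, dimnames = list(nms, NULL))
  expr2 <- expr
  rownames(expr2) <- relabel[nms]
  # BN is excluded: its deterministic lexicographic tie rule is label-aware
  for (m in setdiff(centrality_measures(), "BN")) {
    f <- get(paste0(tolower(m), "_scores"), asNamespace("pecnet"))
    s1 <- if (m %in% c("PeC", "SoPCC")) f(net, expr) else f(net)
    s2 <- if (m %in% c("PeC", "SoPCC")) f(net2, expr2) else f(net2)
    expect_equal(as.numeric(s2[relabel[nms]]), as.numeric(s1[nms]),
                 tolerance = 1e-8, label = m)
  }
})

test_that("centrality_suite returns a full wide table and rejects bad names", {
  fx <- generate_fixture(synthetic_spec(n_nodes = 60, n_clusters = 3,
                                        cluster_size = 6, n_hub_decoys = 2,
                                        hub_degree = 5, seed = 2))
  w <- centrality_suite(fx$network, measures = c("PeC", "DC", "LAC"),
                        expr = fx$expression)
  expect_equal(names(w), c("protein", "PeC", "DC", "LAC"))
  expect_equal(nrow(w), 60L)
  expect_false(is.unsorted(w$protein))
  expect_error(centrality_suite(fx$network, measures = "XX"),
               "unknown measure.*valid names")
  expect_error(centrality_suite(fx$network, measures = "PeC"),
               "needs an expression matrix")
})
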
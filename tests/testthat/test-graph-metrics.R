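as_net <- function(W, density = 0.5, group = "control") {
  # wrap a prebuilt weight matrix without re-thresholding
  structure(list(group = group,
                 roi_labels = colnames(W) %||% sprintf("n%02d", seq_len(nrow(W))),
                 weights = W, density = density,
                 retained_edges = sum(W[upper.tri(W)] > 0)),
            class = "covariance_network")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

triangle3 <- function(w = 1) {
  m <- matrix(w, 3, 3); diag(m) <- 0
  dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
  m
}

test_that("analytic fixtures: complete triangle, path, star, two triangles", {
  gm <- global_metrics(as_net(triangle3(0.5)), modularity_runs = 10, seed = 1)
  expect_equal(gm$transitivity, 1)
  expect_equal(gm$clustering_coefficient, 1)
  expect_equal(gm$path_length, 1 / 0.5)
  expect_equal(gm$n_components, 1L)

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 0.7
  colnames(path) <- rownames(path) <- c("a", "b", "c")
  gp <- global_metrics(as_net(path), modularity_runs = 10, seed = 1)
  expect_equal(gp$transitivity, 0)
  expect_equal(gp$clustering_coefficient, 0)

  two_tri <- matrix(0, 6, 6)
  two_tri[1:3, 1:3] <- triangle3()
  two_tri[4:6, 4:6] <- triangle3()
  colnames(two_tri) <- rownames(two_tri) <- sprintf("n%d", 1:6)
  g2 <- global_metrics(as_net(two_tri), modularity_runs = 10, seed = 1)
  expect_equal(g2$modularity, 0.5, tolerance = 1e-12)
  expect_equal(g2$n_components, 2L)

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  colnames(star) <- rownames(star) <- c("hub", sprintf("leaf%d", 1:4))
  nm <- nodal_metrics(as_net(star))
  expect_equal(nm$degree, c(4L, 1L, 1L, 1L, 1L))
  expect_equal(nm$betweenness, c(1, 0, 0, 0, 0))
  expect_equal(nm$degree_rank, c(1L, 2L, 2L, 2L, 2L))
  expect_equal(nm$closeness[1], 1)
})

test_that("metrics match exhaustive brute-force oracles on small graphs", {
  for (s in 1:40) {
    n <- 4L + s %% 4L
    W <- random_weight_matrix(n, p_edge = 0.55, seed = 7000 + s)
    if (all(W == 0)) next
    net <- as_net(W)
    gm <- global_metrics(net, modularity_runs = 5, seed = s)
    bf <- bf_triangle_metrics(W)
    expect_equal(gm$transitivity, bf$transitivity, tolerance = 1e-9)
    expect_equal(gm$clustering_coefficient, bf$clustering_coefficient,
                 tolerance = 1e-9)
    expect_equal(gm$path_length, bf_path_length(W), tolerance = 1e-9)
    nm <- nodal_metrics(net)
    expect_equal(nm$betweenness, bf_betweenness(W), tolerance = 1e-9)
    expect_equal(nm$closeness, bf_closeness(W), tolerance = 1e-9)
    expect_equal(nm$degree, unname(colSums(W > 0)))
    expect_equal(nm$strength, unname(colSums(W)), tolerance = 1e-12)
  }
})

test_that("betweenness and closeness agree with igraph on larger graphs", {
  W <- random_weight_matrix(20, p_edge = 0.4, seed = 99)
  ig <- igraph::graph_from_adjacency_matrix(W, "undirected", weighted = TRUE)
  nm <- nodal_metrics(as_net(W))
  ib <- igraph::betweenness(ig, weights = 1 / igraph::E(ig)$weight,
                            normalized = TRUE)
  expect_equal(nm$betweenness, unname(ib), tolerance = 1e-9)
  comp <- igraph::components(ig)
  if (comp$no == 1L) {
    ic <- igraph::closeness(ig, weights = 1 / igraph::E(ig)$weight,
                            normalized = TRUE)
    expect_equal(nm$closeness, unname(ic), tolerance = 1e-9)
  }
})

test_that("modularity is a valid Newman Q and improves with restarts", {
  W <- random_weight_matrix(25, p_edge = 0.25, seed = 42)
  # cross-check the reported Q against igraph's evaluation of our partition
  lv <- scovnet:::cpp_louvain(W, 10L, 7)
  ig <- igraph::graph_from_adjacency_matrix(W, "undirected", weighted = TRUE)
  expect_equal(lv$modularity,
               igraph::modularity(ig, lv$membership,
                                  weights = igraph::E(ig)$weight),
               tolerance = 1e-12)
  # complete uniform graph: best partition is one community, Q = 0
  K <- matrix(0.7, 8, 8); diag(K) <- 0
  expect_equal(scovnet:::cpp_louvain(K, 10L, 3)$modularity, 0,
               tolerance = 1e-12)
  # prefix property of the restart stream
  q1 <- scovnet:::cpp_louvain(W, 1L, 11)$modularity
  q5 <- scovnet:::cpp_louvain(W, 5L, 11)$modularity
  q20 <- scovnet:::cpp_louvain(W, 20L, 11)$modularity
  expect_lte(q1, q5)
  expect_lte(q5, q20)
  expect_gte(q1, -0.5)
  expect_lte(q20, 1)
})

test_that("metrics respond to weight rescaling as dimensional analysis says", {
  W <- random_weight_matrix(12, p_edge = 0.5, seed = 1234)
  c_scale <- 3.7
  g1 <- global_metrics(as_net(W), modularity_runs = 5, seed = 2)
  g2 <- global_metrics(as_net(W * c_scale), modularity_runs = 5, seed = 2)
  expect_equal(g1$transitivity, g2$transitivity, tolerance = 1e-12)
  expect_equal(g1$clustering_coefficient, g2$clustering_coefficient,
               tolerance = 1e-12)
  expect_equal(g1$modularity, g2$modularity, tolerance = 1e-12)
  expect_equal(g1$path_length, g2$path_length * c_scale, tolerance = 1e-9)
  n1 <- nodal_metrics(as_net(W))
  n2 <- nodal_metrics(as_net(W * c_scale))
  expect_equal(n1$degree, n2$degree)
  expect_equal(n2$strength, n1$strength * c_scale, tolerance = 1e-9)
  expect_equal(order(n1$betweenness), order(n2$betweenness))
})

test_that("degenerate graphs are rejected or handled", {
  empty <- matrix(0, 4, 4)
  expect_error(global_metrics(as_net(empty)), "empty graph")
  expect_error(nodal_metrics(matrix(c(0, -1, -1, 0), 2)), "nonnegative")
  expect_error(global_metrics(as_net(matrix(1, 3, 3))), "diagonal")
})
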
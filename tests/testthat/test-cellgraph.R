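test_that("distance metrics map to [0,1] similarities with the right endpoints", {
  vals <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4))
  x <- expression_matrix(vals)
  for (metric in c("ed", "md")) {
    g <- pairwise_similarity(x, metric)
    expect_equal(g$weights["a", "b"], 1)        # identical cells -> d = 0 -> s = 1
    expect_equal(min(g$weights[upper.tri(g$weights)]), 0)  # pair at d_max -> s = 0
    expect_true(all(g$weights >= 0 & g$weights <= 1))
    expect_identical(diag(g$weights), setNames(rep(0, 3), rownames(vals)))
  }
})

test_that("ED similarity ordering is the reverse of the distance ordering", {
  sim <- simulate_cells(n_cells = 15, n_genes = 30, k_true = 2, seed = 3)
  g <- pairwise_similarity(sim$x, "ed")
  d <- as.matrix(dist(sim$x$values))
  up <- upper.tri(d)
  expect_equal(order(d[up]), order(-g$weights[up]))
})

test_that("correlation metrics clamp negatives and handle constant cells", {
  x <- expression_matrix(rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1)))
  g <- pairwise_similarity(x, "pcc")
  expect_equal(g$weights["a", "b"], 1)   # perfectly correlated
  expect_equal(g$weights["a", "c"], 0)   # r = -1, clamped
  expect_identical(g$weights, t(g$weights))

  with_const <- expression_matrix(rbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_warning(gc2 <- pairwise_similarity(with_const, "pcc"), "constant")
  expect_equal(gc2$weights["a", "b"], 0)
})

test_that("SNN counts shared Euclidean neighbourhoods excluding self", {
  # two tight pairs far apart: with k = 1 each cell's neighbour is its twin
  vals <- rbind(a = c(0, 0), b = c(0.1, 0), c = c(10, 0), d = c(10.1, 0))
  g <- pairwise_similarity(expression_matrix(vals), "snn", snn_k = 1)
  expect_equal(g$weights["a", "b"], 0)   # a's NN is b, b's NN is a: no shared cell
  g2 <- pairwise_similarity(expression_matrix(vals), "snn", snn_k = 2)
  expect_equal(g2$weights["a", "b"], 0.5)  # kNN(a) = {b,c}, kNN(b) = {a,c}: share c
  expect_true(all(g2$weights >= 0 & g2$weights <= 1))
  expect_error(pairwise_similarity(expression_matrix(vals), "snn", snn_k = 4),
               "snn_k")
})

test_that("core selection keeps the strongest edge quantile including ties", {
  # 4 cells, 6 edges: 0.9, 0.8, 0.7, 0.3, 0.2, 0.1; quarter of 6 -> keep 2
  g <- graph_from_edges(4, rbind(c(1, 2, 0.9), c(1, 3, 0.8), c(1, 4, 0.7),
                                 c(2, 3, 0.3), c(2, 4, 0.2), c(3, 4, 0.1)))
  cs <- select_core_cells(g, 0.25)
  expect_equal(cs$split$retained_edge_count, 2L)
  expect_equal(cs$split$s_c, 0.8)
  expect_setequal(cs$split$core_cell_ids, c("c1", "c2", "c3"))
  expect_identical(cs$split$noncore_cell_ids, "c4")
  # edges tied with the threshold weight are all retained
  g_tie <- graph_from_edges(4, rbind(c(1, 2, 0.9), c(1, 3, 0.8), c(1, 4, 0.8),
                                     c(2, 3, 0.3), c(2, 4, 0.2), c(3, 4, 0.1)))
  cs_tie <- select_core_cells(g_tie, 0.25)
  expect_equal(cs_tie$split$retained_edge_count, 3L)
})

test_that("edge_fraction = 1 keeps the whole graph and all cells core", {
  sim <- simulate_cells(n_cells = 20, n_genes = 40, k_true = 2, seed = 8)
  g <- pairwise_similarity(sim$x, "pcc")
  cs <- select_core_cells(g, 1)
  expect_length(cs$split$noncore_cell_ids, 0L)
  expect_setequal(cs$split$core_cell_ids, cell_ids(sim$x))
})

test_that("core and non-core sets partition the cells and grow monotonically", {
  sim <- simulate_cells(n_cells = 40, n_genes = 60, k_true = 3,
                        boundary_fraction = 0.2, seed = 4)
  g <- pairwise_similarity(sim$x, "pcc")
  prev_core <- character(0)
  for (f in c(0.1, 0.25, 0.5, 1)) {
    cs <- select_core_cells(g, f)
    expect_setequal(c(cs$split$core_cell_ids, cs$split$noncore_cell_ids),
                    cell_ids(sim$x))
    expect_length(intersect(cs$split$core_cell_ids, cs$split$noncore_cell_ids), 0L)
    expect_gte(cs$split$retained_edge_count,
               ceiling(f * choose(40, 2)) -
                 sum(g$weights[upper.tri(g$weights)] == 0))
    expect_true(all(prev_core %in% cs$split$core_cell_ids))
    prev_core <- cs$split$core_cell_ids
    # every core cell touches a retained edge
    deg <- rowSums(cs$graph$weights)
    expect_true(all(deg > 0))
  }
})

test_that("core cells are enriched near their planted centroids", {
  sim <- simulate_cells(n_cells = 100, n_genes = 200, k_true = 3,
                        boundary_fraction = 0.25, separation = 8,
                        skew_mode = "uniform", seed = 6)
  pre <- maybe_log_transform(sim$x)$x
  g <- pairwise_similarity(pre, "pcc")
  cs <- select_core_cells(g, 0.25)
  expect_gt(length(cs$split$noncore_cell_ids), 0)
  # distance of each cell to its own cluster's mean profile
  centroid_dist <- function(ids) {
    mean(vapply(ids, function(id) {
      lab <- sim$labels[id]
      own <- pre$values[names(sim$labels)[sim$labels == lab], , drop = FALSE]
      sqrt(sum((pre$values[id, ] - colMeans(own))^2))
    }, numeric(1)))
  }
  expect_lt(centroid_dist(cs$split$core_cell_ids),
            centroid_dist(cs$split$noncore_cell_ids))
})
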
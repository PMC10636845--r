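# random small core graph with distinct weights (connected via a cycle)
random_core_graph <- function(n, seed) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- runif(1, 0.3, 1)
  w[1, n] <- w[n, 1] <- runif(1, 0.3, 1)
  extra <- which(upper.tri(w) & w == 0)
  extra <- sample(extra, min(n, length(extra)))
  w[extra] <- runif(length(extra), 0.05, 0.9)
  w <- pmax(w, t(w))
  graph_from_weights(w)
}

partition_list <- function(labels) split(seq_along(labels), labels)

test_that("cell-to-cluster distance matches its two definitions", {
  g <- random_core_graph(6, seed = 21)
  p <- walk_probabilities(g, t = 4)
  # singleton, literal mode: exactly the walk probability
  expect_equal(cluster_cell_distance(2, 5, p, "literal"), p$probs[2, 5])
  # walktrap mode: a cell against its own singleton is at distance zero
  expect_equal(cluster_cell_distance(3, 3, p, "walktrap"), 0)
  # two-cell cluster, literal mode: arithmetic mean of the two probabilities
  expect_equal(cluster_cell_distance(c(1, 4), 6, p, "literal"),
               (p$probs[1, 6] + p$probs[4, 6]) / 2)
  # walktrap general case against the direct formula
  expect_equal(cluster_cell_distance(c(2, 3, 5), 1, p, "walktrap"),
               ccd_bruteforce(c(2, 3, 5), 1, p$probs, p$degrees, "walktrap"))
  expect_error(cluster_cell_distance(integer(0), 1, p), "empty cluster")
})

test_that("cluster-to-cluster distance collapses to the walk distance for singletons", {
  g <- random_core_graph(6, seed = 22)
  p <- walk_probabilities(g, t = 4)
  d <- rw_distance(p)
  for (i in 1:3) for (j in 4:6)
    expect_equal(cluster_cluster_distance(i, j, p), d[i, j], tolerance = 1e-12)
  expect_equal(cluster_cluster_distance(2, 2, p), 0)
  # two 2-cell clusters: term-by-term evaluation
  di <- colMeans(p$probs[c(1, 2), ]); dj <- colMeans(p$probs[c(4, 5), ])
  expect_equal(cluster_cluster_distance(c(1, 2), c(4, 5), p),
               sqrt(sum((di - dj)^2 / p$degrees)))
  expect_error(cluster_cluster_distance(c(1, 2), c(2, 3), p), "overlapping")
})

test_that("merge cost equals the full sigma recomputation in both modes", {
  for (seed in c(31, 32)) {
    g <- random_core_graph(9, seed = seed)
    p <- walk_probabilities(g, t = 4)
    for (mode in c("walktrap", "literal")) {
      state <- agglomerate(p, mode = mode)
      for (step in seq_len(state$n - 1)) {
        before <- partition_list(cut_clusters(state, state$n - step + 1))
        after <- partition_list(cut_clusters(state, state$n - step))
        delta_bf <- sigma_bruteforce(after, p$probs, p$degrees, mode) -
          sigma_bruteforce(before, p$probs, p$degrees, mode)
        expect_equal(state$merges$dsigma[step], delta_bf, tolerance = 1e-10)
        # and the exported merge_cost agrees for the merged pair: the cluster
        # in `after` absent from `before` is the union of two `before` clusters
        is_new <- vapply(after, function(cl)
          !any(vapply(before, function(b) setequal(b, cl), TRUE)), TRUE)
        merged <- after[[which(is_new)[1]]]
        ci <- before[[which(vapply(before, function(b)
          all(b %in% merged) && length(b) < length(merged), TRUE))[1]]]
        cj <- setdiff(merged, ci)
        expect_equal(merge_cost(ci, cj, p, mode), delta_bf, tolerance = 1e-10)
      }
    }
  }
})

test_that("each merge is the cheapest available pair (exhaustive check)", {
  g <- random_core_graph(8, seed = 41)
  p <- walk_probabilities(g, t = 4)
  state <- agglomerate(p, mode = "walktrap")
  for (step in seq_len(state$n - 2)) {
    before <- partition_list(cut_clusters(state, state$n - step + 1))
    costs <- c()
    for (i in seq_along(before)) for (j in seq_along(before)) {
      if (i < j) costs <- c(costs, merge_cost(before[[i]], before[[j]], p, "walktrap"))
    }
    expect_equal(state$merges$dsigma[step], min(costs), tolerance = 1e-10)
  }
})

test_that("agglomeration runs the smallest instance and respects graph symmetry", {
  g2 <- graph_from_edges(2, rbind(c(1, 2, 1)))
  st <- agglomerate(walk_probabilities(g2, t = 2))
  expect_equal(nrow(st$merges), 1L)

  # two equal-weight triangles joined by a weak bridge: within-triangle
  # merges come first, and sigma_K is non-increasing in K
  g <- two_clique_graph(size = 3, w_in = 1, w_bridge = 0.05)
  p <- walk_probabilities(g, t = 4)
  st2 <- agglomerate(p)
  first3 <- st2$merges[1:3, c("a", "b")]
  same_side <- function(a, b) (a <= 3) == (b <= 3)
  expect_true(all(mapply(same_side, first3$a, first3$b)))
  expect_true(all(diff(st2$sigma) <= 1e-12))   # sigma[K] decreasing in K
})

test_that("the partition is equivariant under relabelling of the input cells", {
  sim <- simulate_cells(n_cells = 36, n_genes = 80, k_true = 3, seed = 13)
  pre <- maybe_log_transform(sim$x)$x
  run_labels <- function(x) {
    g <- pairwise_similarity(x, "pcc")
    cs <- select_core_cells(g, 1)   # all cells core: label vectors comparable
    st <- agglomerate(walk_probabilities(cs$graph, 4))
    cut_clusters(st, 3)
  }
  lab1 <- run_labels(pre)
  set.seed(99)
  perm <- sample(nrow(pre$values))
  lab2 <- run_labels(expression_matrix(pre$values[perm, ],
                                       log_transformed = TRUE))
  common <- names(lab1)
  expect_equal(ari_paircount(lab1[common], lab2[common]), 1)
})

test_that("the selected cluster count matches planted structure", {
  # two cliques -> K = 2
  g <- two_clique_graph(size = 4, w_in = 1, w_bridge = 0.05)
  st <- agglomerate(walk_probabilities(g, t = 4))
  expect_equal(select_k(st), 2L)

  # three well-separated planted clusters -> K = 3
  sim <- simulate_cells(n_cells = 60, n_genes = 150, k_true = 3,
                        separation = 8, skew_mode = "uniform", seed = 17)
  pre <- maybe_log_transform(sim$x)$x
  cs <- select_core_cells(pairwise_similarity(pre, "pcc"), 0.25)
  st3 <- agglomerate(walk_probabilities(cs$graph, 4))
  expect_equal(select_k(st3), 3L)
})

test_that("degenerate sigma plateaus fall back to k_min with a warning", {
  flat <- structure(list(merges = data.frame(a = c(1, 1, 1), b = c(2, 3, 4),
                                             dsigma = c(0, 0, 0)),
                         sigma = rep(0, 4), n = 4L, mode = "walktrap",
                         cell_ids = paste0("c", 1:4)),
                    class = "ClusterState")
  expect_warning(k <- select_k(flat), "degenerate")
  expect_equal(k, 2L)
})
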
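# First clustering step: bottom-up merging of core cells under a Ward-style
# criterion on the random-walk geometry.
#
# Two readings of the cell-to-cluster distance are supported:
#   * "walktrap" (default): d(C, k) is the degree-weighted L2 distance between
#     the cluster's averaged probability row and the cell's row — the distance
#     the rest of the machinery (cluster-cluster distance, merge cost) treats
#     it as. With this reading the merge cost is a genuine Ward criterion and
#     reduces to a centroid computation on degree-rescaled probability rows.
#   * "literal": d(C, k) is the plain average of the walk probabilities
#     P_ik over cluster members i — a similarity-flavoured quantity, exposed
#     for comparison.

# degree-rescaled probability rows: Q[i, k] = P[i, k] / sqrt(Deg(k)), so that
# plain Euclidean geometry on Q is the degree-weighted geometry on P
.walk_q <- function(p) sweep(p$probs, 2L, sqrt(p$degrees), "/")

#' Distance between a cell and a cluster of core cells
#'
#' In `"walktrap"` mode (the default used throughout the pipeline), the
#' degree-weighted L2 distance between the cluster's mean walk-probability
#' row and the cell's row. In `"literal"` mode, the average probability
#' `mean(P[i, k])` over cluster members `i` of reaching cell `k`.
#'
#' @param members Integer indices (or cell ids) of the cluster's cells.
#' @param k Index (or id) of the target core cell.
#' @param p A `WalkProfile`.
#' @param mode `"walktrap"` or `"literal"`.
#' @return A single numeric value.
#' @export
cluster_cell_distance <- function(members, k, p, mode = c("walktrap", "literal")) {
  stopifnot(inherits(p, "WalkProfile"))
  mode <- match.arg(mode)
  members <- .resolve_cells(members, p)
  k <- .resolve_cells(k, p)
  if (length(members) == 0L) stop("empty cluster")
  if (mode == "literal") {
    mean(p$probs[members, k])
  } else {
    q <- .walk_q(p)
    qc <- colMeans(q[members, , drop = FALSE])
    sqrt(sum((qc - q[k, ])^2))
  }
}

#' Distance between two clusters of core cells
#'
#' Degree-weighted L2 distance between the two clusters' averaged
#' walk-probability rows,
#' \deqn{d_{C_i C_j} = \sqrt{\sum_k (d_{C_i k} - d_{C_j k})^2 / Deg(k)},}
#' where \eqn{d_{Ck}} is the average probability of reaching cell k from the
#' cluster. For two singletons this collapses to the random-walk distance
#' between the two cells ([rw_distance()]).
#'
#' @param ci,cj Integer indices (or cell ids) of the two disjoint clusters.
#' @param p A `WalkProfile`.
#' @return A single numeric value.
#' @export
cluster_cluster_distance <- function(ci, cj, p) {
  stopifnot(inherits(p, "WalkProfile"))
  ci <- .resolve_cells(ci, p); cj <- .resolve_cells(cj, p)
  if (length(ci) == 0L || length(cj) == 0L) stop("empty cluster")
  if (length(intersect(ci, cj)) &&
      !(length(ci) == length(cj) && all(sort(ci) == sort(cj))))
    stop("overlapping clusters")
  di <- colMeans(p$probs[ci, , drop = FALSE])
  dj <- colMeans(p$probs[cj, , drop = FALSE])
  sqrt(sum((di - dj)^2 / p$degrees))
}

#' Ward-style cost of merging two clusters
#'
#' The change in the average intra-cluster squared distance caused by merging
#' `ci` and `cj` into their union `cu`:
#' \deqn{\Delta\sigma = \frac{1}{n}\Big(\sum_{k \in C_u} d_{C_u k}^2
#'   - \sum_{k \in C_i} d_{C_i k}^2 - \sum_{k \in C_j} d_{C_j k}^2\Big),}
#' with `d` per [cluster_cell_distance()] in the chosen mode and `n` the
#' number of core cells. At every step [agglomerate()] merges the pair with
#' the smallest cost.
#'
#' @inheritParams cluster_cell_distance
#' @param ci,cj Integer indices (or cell ids) of two disjoint clusters.
#' @return A single numeric value.
#' @export
merge_cost <- function(ci, cj, p, mode = c("walktrap", "literal")) {
  stopifnot(inherits(p, "WalkProfile"))
  mode <- match.arg(mode)
  ci <- .resolve_cells(ci, p); cj <- .resolve_cells(cj, p)
  if (length(intersect(ci, cj))) stop("clusters must be disjoint")
  n <- nrow(p$probs)
  cu <- c(ci, cj)
  ss <- function(members) {
    d2 <- vapply(members, function(k)
      cluster_cell_distance(members, k, p, mode)^2, numeric(1))
    sum(d2)
  }
  (ss(cu) - ss(ci) - ss(cj)) / n
}

.resolve_cells <- function(idx, p) {
  if (is.character(idx)) {
    out <- match(idx, rownames(p$probs))
    if (anyNA(out)) stop("unknown cell id(s): ", paste(idx[is.na(out)], collapse = ", "))
    out
  } else {
    as.integer(idx)
  }
}

#' Hierarchical clustering of core cells by iterative cheapest merges
#'
#' Starts from singleton clusters and repeatedly merges the pair with the
#' smallest merge cost ([merge_cost()]) until one cluster remains, recording
#' the merge trace and the average intra-cluster squared distance
#' \eqn{\sigma_K} at every level K. Ties in the merge cost are broken by the
#' lexicographically smallest pair of cluster ids, making the procedure
#' deterministic and equivariant under relabelling of the input cells.
#'
#' Cluster ids are the smallest original cell index in the cluster; a merged
#' cluster inherits the smaller of its parents' ids.
#'
#' @param p A `WalkProfile` over at least 2 core cells.
#' @param mode Cell-to-cluster distance mode; see [cluster_cell_distance()].
#' @return An object of class `ClusterState`: `merges` (data.frame with
#'   columns `a`, `b`, `dsigma`, one row per merge), `sigma` (numeric vector,
#'   `sigma[K]` = \eqn{\sigma_K}), `n`, `mode`, `cell_ids`.
#' @export
agglomerate <- function(p, mode = c("walktrap", "literal")) {
  stopifnot(inherits(p, "WalkProfile"))
  mode <- match.arg(mode)
  n <- nrow(p$probs)
  if (n < 2L) stop("need at least 2 core cells")
  if (mode == "walktrap") .agglomerate_walktrap(p) else .agglomerate_literal(p)
}

# Shared driver: given an initial pairwise cost matrix and closures that
# merge bookkeeping and refresh the costs of the new cluster against the
# rest, run the n-1 cheapest-merge steps with deterministic tie-breaking.
.run_merges <- function(n, ids, cost, sigma_start, merge_update) {
  active <- rep(TRUE, n)
  merges <- data.frame(a = integer(n - 1L), b = integer(n - 1L),
                       dsigma = numeric(n - 1L))
  sigma <- numeric(n)
  sigma[n] <- sigma_start
  for (step in seq_len(n - 1L)) {
    mval <- min(cost)
    cand <- which(cost == mval, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_ids <- cbind(pmin(ids[cand[, 1L]], ids[cand[, 2L]]),
                      pmax(ids[cand[, 1L]], ids[cand[, 2L]]))
    pick <- order(pair_ids[, 1L], pair_ids[, 2L])[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
    merges$a[step] <- a; merges$b[step] <- b; merges$dsigma[step] <- mval
    K <- n - step
    sigma[K] <- sigma[K + 1L] + mval
    # keep position i as the merged cluster, retire position j
    active[j] <- FALSE
    ids[i] <- a
    cost[j, ] <- Inf; cost[, j] <- Inf
    cost <- merge_update(i, j, cost, active)
  }
  list(merges = merges, sigma = sigma)
}

.agglomerate_walktrap <- function(p) {
  q <- .walk_q(p)
  n <- nrow(q)
  cent <- q                     # cluster centroids in degree-rescaled space
  sizes <- rep(1L, n)
  # Ward cost between clusters u, v: (s_u s_v / (s_u + s_v)) ||cent_u - cent_v||^2 / n
  cost <- as.matrix(stats::dist(q))^2 / (2 * n)
  diag(cost) <- Inf
  env <- environment()
  merge_update <- function(i, j, cost, active) {
    su <- env$sizes[i] + env$sizes[j]
    env$cent[i, ] <- (env$sizes[i] * env$cent[i, ] + env$sizes[j] * env$cent[j, ]) / su
    env$sizes[i] <- su
    others <- which(active & seq_len(n) != i)
    if (length(others)) {
      d2 <- rowSums((env$cent[others, , drop = FALSE] -
                       rep(env$cent[i, ], each = length(others)))^2)
      newc <- (env$sizes[others] * su / (env$sizes[others] + su)) * d2 / n
      cost[i, others] <- newc
      cost[others, i] <- newc
      cost[i, i] <- Inf
    }
    cost
  }
  res <- .run_merges(n, seq_len(n), cost, sigma_start = 0, merge_update)
  structure(list(merges = res$merges, sigma = res$sigma, n = n,
                 mode = "walktrap", cell_ids = rownames(p$probs)),
            class = "ClusterState")
}

.agglomerate_literal <- function(p) {
  pr <- p$probs
  n <- nrow(pr)
  members <- lapply(seq_len(n), identity)
  pmean <- pr                   # cluster-averaged probability rows
  sizes <- rep(1L, n)
  ss <- pr[cbind(seq_len(n), seq_len(n))]^2   # singleton: d_Ck = P_kk
  pair_cost <- function(i, j) {
    mu <- c(members[[i]], members[[j]])
    pu <- (sizes[i] * pmean[i, ] + sizes[j] * pmean[j, ]) / (sizes[i] + sizes[j])
    (sum(pu[mu]^2) - ss[i] - ss[j]) / n
  }
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
    cost[i, j] <- cost[j, i] <- pair_cost(i, j)
  env <- environment()
  merge_update <- function(i, j, cost, active) {
    su <- env$sizes[i] + env$sizes[j]
    env$pmean[i, ] <- (env$sizes[i] * env$pmean[i, ] + env$sizes[j] * env$pmean[j, ]) / su
    env$members[[i]] <- c(env$members[[i]], env$members[[j]])
    env$sizes[i] <- su
    env$ss[i] <- sum(env$pmean[i, env$members[[i]]]^2)
    others <- which(active & seq_len(n) != i)
    for (v in others) {
      cv <- pair_cost(i, v)
      cost[i, v] <- cv; cost[v, i] <- cv
    }
    cost[i, i] <- Inf
    cost
  }
  res <- .run_merges(n, seq_len(n), cost,
                     sigma_start = sum(ss) / n, merge_update)
  structure(list(merges = res$merges, sigma = res$sigma, n = n,
                 mode = "literal", cell_ids = rownames(p$probs)),
            class = "ClusterState")
}

#' @export
print.ClusterState <- function(x, ...) {
  cat(sprintf("ClusterState: %d core cells, %d merges recorded (%s mode)\n",
              x$n, nrow(x$merges), x$mode))
  invisible(x)
}

#' Partition of the core cells at a given number of clusters
#'
#' Replays the merge trace of [agglomerate()] down to `k` clusters.
#'
#' @param state A `ClusterState`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels in `1..k`, named by cell id.
#' @export
cut_clusters <- function(state, k) {
  stopifnot(inherits(state, "ClusterState"))
  n <- state$n
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]")
  lab <- seq_len(n)
  nm <- n - k
  for (step in seq_len(nm)) {
    lab[lab == state$merges$b[step]] <- state$merges$a[step]
  }
  lab <- match(lab, sort(unique(lab)))
  names(lab) <- state$cell_ids
  lab
}

#' Automatic selection of the number of clusters
#'
#' Scans the \eqn{\sigma_K} profile recorded by [agglomerate()] and picks the
#' K at which the next merge (K to K-1 clusters) is most expensive relative
#' to the previous one (K+1 to K):
#' \deqn{\eta_K = \frac{\sigma_{K-1} - \sigma_K}{\sigma_K - \sigma_{K+1}},}
#' maximised over `K` in `[k_min, k_max]`. A large \eqn{\eta_K} marks the
#' level just before an expensive merge — the natural place to stop: further
#' merging would fuse genuinely distinct groups.
#'
#' Levels where the denominator vanishes (a plateau in \eqn{\sigma}) are
#' skipped with a warning; if every level in range is degenerate, `k_min` is
#' returned with a warning.
#'
#' @param state A `ClusterState`.
#' @param k_min,k_max Search range; `k_max` defaults to `min(50, n - 1)`.
#' @return The selected number of clusters (integer).
#' @export
select_k <- function(state, k_min = 2, k_max = NULL) {
  stopifnot(inherits(state, "ClusterState"))
  n <- state$n
  if (is.null(k_max)) k_max <- min(50L, n - 1L)
  k_max <- min(k_max, n - 1L)
  if (k_min < 2L) stop("k_min must be >= 2")
  if (k_min > k_max) return(as.integer(min(k_min, n)))
  ks <- seq.int(k_min, k_max)
  num <- state$sigma[ks - 1L] - state$sigma[ks]
  den <- state$sigma[ks] - state$sigma[ks + 1L]
  eta <- ifelse(den == 0, NA_real_, num / den)
  if (anyNA(eta)) {
    if (all(is.na(eta))) {
      warning("sigma profile degenerate everywhere; falling back to k_min")
      return(as.integer(k_min))
    }
    warning("sigma plateau at K = ",
            paste(ks[is.na(eta)], collapse = ", "), "; level(s) skipped")
  }
  as.integer(ks[which.max(eta)])
}
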
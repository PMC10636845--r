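#' Transition matrix of the random walk on the core-cell graph
#'
#' Row-stochastic matrix `M` with `M[i, j] = w_ij / Deg(i)`, where
#' `Deg(i) = sum_j w_ij` is cell i's weighted degree over its neighbours.
#' The diagonal is zero (no self-loops).
#'
#' @param g_cc A `CellGraph` restricted to core cells (see
#'   [select_core_cells()]).
#' @return A row-stochastic numeric matrix.
#' @export
transition_matrix <- function(g_cc) {
  stopifnot(inherits(g_cc, "CellGraph"))
  w <- g_cc$weights
  if (nrow(w) == 0L) stop("empty core graph")
  deg <- rowSums(w)
  if (any(deg <= 0)) stop("isolated node in core graph")
  w / deg
}

#' t-step walk probabilities from every core cell
#'
#' A walker started at core cell i with probability vector `e_i` follows the
#' transition matrix for `t` steps; row i of the result is the probability of
#' finding it at each core cell after `t` steps, i.e. row i of `M^t`. Two
#' cells lying in the same densely connected region "see" the graph alike, so
#' their probability rows are close — this is what the random-walk distance
#' ([rw_distance()]) measures. The matrix power is computed exactly by
#' repeated squaring.
#'
#' `t` trades off locality against mixing: too small and the walk has not
#' explored the cell's neighbourhood; too large and every row approaches the
#' stationary distribution (proportional to degree), erasing all contrast.
#' `t = 4` is the default.
#'
#' @param g_cc A `CellGraph` over core cells.
#' @param t Integer number of walk steps (`t >= 0`; `t = 0` gives the
#'   identity).
#' @return An object of class `WalkProfile`: `probs` (n x n matrix, rows
#'   summing to 1), `degrees` (weighted degrees of the core graph), `t`.
#' @export
walk_probabilities <- function(g_cc, t = 4) {
  stopifnot(inherits(g_cc, "CellGraph"))
  t <- as.integer(t)
  if (t < 0) stop("t must be >= 0")
  m <- transition_matrix(g_cc)
  n <- nrow(m)
  p <- diag(n)
  base <- m
  k <- t
  while (k > 0) {  # exponentiation by squaring
    if (k %% 2L == 1L) p <- p %*% base
    k <- k %/% 2L
    if (k > 0) base <- base %*% base
  }
  dimnames(p) <- dimnames(m)
  structure(list(probs = p, degrees = rowSums(g_cc$weights), t = t),
            class = "WalkProfile")
}

#' @export
print.WalkProfile <- function(x, ...) {
  cat(sprintf("WalkProfile: %d core cells, t = %d steps\n",
              nrow(x$probs), x$t))
  invisible(x)
}

#' Random-walk distance between core cells
#'
#' The degree-weighted L2 distance between two cells' t-step walk-probability
#' rows:
#' \deqn{d_{ij} = \sqrt{\sum_k (P_{ik}^t - P_{jk}^t)^2 / Deg(k)}.}
#' Down-weighting by `Deg(k)` discounts heavily connected cells that every
#' walk visits often regardless of its start. Cells in the same dense region
#' are close; as `t` grows on a connected non-bipartite graph all rows
#' converge to the stationary distribution and all distances shrink to zero.
#'
#' @param p A `WalkProfile`.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
rw_distance <- function(p) {
  stopifnot(inherits(p, "WalkProfile"))
  q <- sweep(p$probs, 2L, sqrt(p$degrees), "/")
  d <- as.matrix(stats::dist(q))
  dimnames(d) <- dimnames(p$probs)
  d
}
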
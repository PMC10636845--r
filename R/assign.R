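# Second clustering step: cluster centers in expression space and
# nearest-center assignment of the non-core cells.

#' Cluster centers in expression space
#'
#' The center of cluster k is the per-gene arithmetic mean of the expression
#' profiles of its core cells,
#' \deqn{c_{kj} = \frac{1}{|\chi_k|} \sum_{x_c \in \chi_k} x_{cj},}
#' computed on the preprocessed (possibly log-transformed) matrix.
#'
#' @param x The preprocessed `ExpressionMatrix` over all cells.
#' @param core_labels Integer cluster labels in `1..K`, named by core-cell
#'   id (as returned by [cut_clusters()]).
#' @return A K x p numeric matrix of center profiles, rows named
#'   `cluster_1 ... cluster_K`.
#' @export
compute_centers <- function(x, core_labels) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(names(core_labels))) stop("core_labels must be named by cell id")
  idx <- match(names(core_labels), cell_ids(x))
  if (anyNA(idx)) stop("core_labels contain unknown cell ids")
  k <- max(core_labels)
  if (!setequal(unique(core_labels), seq_len(k))) stop("empty cluster in core_labels")
  centers <- matrix(0, k, ncol(x$values),
                    dimnames = list(paste0("cluster_", seq_len(k)), gene_ids(x)))
  for (cl in seq_len(k)) {
    centers[cl, ] <- colMeans(x$values[idx[core_labels == cl], , drop = FALSE])
  }
  centers
}

#' Assign non-core cells to their nearest cluster center
#'
#' Each non-core cell receives the label of the center closest to it in the
#' preprocessed expression space; assignment is a single pass (centers are
#' not re-estimated). Distance ties go to the smallest cluster id.
#'
#' @param x The preprocessed `ExpressionMatrix` over all cells.
#' @param centers Center matrix from [compute_centers()].
#' @param noncore_ids Character vector of non-core cell ids (may be empty).
#' @param method `"euclidean"` (default) or `"pcc"` (one minus Pearson
#'   correlation, matching a correlation-built cell graph).
#' @return Integer vector of cluster labels in `1..K`, named by non-core
#'   cell id.
#' @export
assign_noncore <- function(x, centers, noncore_ids,
                           method = c("euclidean", "pcc")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  method <- match.arg(method)
  if (nrow(centers) == 0L) stop("no clusters to assign to")
  if (length(noncore_ids) == 0L)
    return(stats::setNames(integer(0), character(0)))
  idx <- match(noncore_ids, cell_ids(x))
  if (anyNA(idx)) stop("unknown non-core cell id(s)")
  v <- x$values[idx, , drop = FALSE]
  d <- if (method == "euclidean") {
    # squared distances via the expansion ||v||^2 - 2 v.c + ||c||^2
    outer(rowSums(v^2), rep(1, nrow(centers))) -
      2 * tcrossprod(v, centers) +
      outer(rep(1, nrow(v)), rowSums(centers^2))
  } else {
    r <- suppressWarnings(stats::cor(t(v), t(centers)))
    r[is.na(r)] <- 0
    1 - r
  }
  lab <- apply(d, 1L, which.min)   # which.min takes the first (smallest id) on ties
  stats::setNames(as.integer(lab), noncore_ids)
}
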
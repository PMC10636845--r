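#' Pairwise cell-similarity graph
#'
#' Builds the fully connected weighted graph over cells whose edge weights are
#' similarities in `[0, 1]`:
#'
#' * `ed` / `md` — Euclidean / Manhattan distance, rescaled to similarity by
#'   `s = 1 - d / d_max` with `d_max` the largest pairwise distance;
#' * `pcc` / `scc` — Pearson / Spearman correlation between cell profiles,
#'   with negative coefficients clamped to 0 (an anti-correlated pair carries
#'   no edge);
#' * `snn` — shared-nearest-neighbour overlap `|kNN(i) ∩ kNN(j)| / k`, where
#'   neighbourhoods are the `snn_k` Euclidean nearest neighbours excluding the
#'   cell itself.
#'
#' Self-similarities are not stored: the diagonal is zero, so that node
#' degrees sum over neighbours only.
#'
#' @param x An `ExpressionMatrix` with at least 2 cells (preprocessed; see
#'   [maybe_log_transform()]).
#' @param metric One of `"ed"`, `"md"`, `"pcc"`, `"scc"`, `"snn"`. Pearson
#'   correlation is the default (the best performer of the five on real
#'   benchmarks).
#' @param snn_k Neighbourhood size for the SNN metric; must be smaller than
#'   the number of cells.
#' @return An object of class `CellGraph`: list with `weights` (symmetric
#'   matrix, zero diagonal), `metric`, `snn_k`.
#' @export
pairwise_similarity <- function(x, metric = c("pcc", "scc", "ed", "md", "snn"),
                                snn_k = 20) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  metric <- match.arg(metric)
  vals <- x$values
  m <- nrow(vals)
  if (m < 2L) stop("need at least 2 cells")
  w <- switch(metric,
    ed = , md = {
      d <- as.matrix(stats::dist(vals, method = if (metric == "ed") "euclidean" else "manhattan"))
      dmax <- max(d)
      if (dmax == 0) {
        warning("all cells identical; all similarities set to 1")
        s <- matrix(1, m, m)
      } else {
        s <- 1 - d / dmax
      }
      s
    },
    pcc = , scc = {
      r <- suppressWarnings(
        stats::cor(t(vals), method = if (metric == "pcc") "pearson" else "spearman"))
      if (anyNA(r)) {
        warning("constant cell profile(s): undefined correlations set to 0")
        r[is.na(r)] <- 0
      }
      pmax(r, 0)
    },
    snn = {
      if (snn_k >= m) stop("snn_k must be smaller than the number of cells")
      d <- as.matrix(stats::dist(vals))
      diag(d) <- Inf
      nn <- apply(d, 1L, function(row) order(row)[seq_len(snn_k)])  # snn_k x m
      inc <- matrix(0L, m, m)  # inc[j, i] = 1 if j is a neighbour of i
      inc[cbind(as.vector(nn), rep(seq_len(m), each = snn_k))] <- 1L
      crossprod(inc) / snn_k
    })
  diag(w) <- 0
  dimnames(w) <- list(rownames(vals), rownames(vals))
  structure(list(weights = w, metric = metric,
                 snn_k = if (metric == "snn") snn_k else NA_integer_),
            class = "CellGraph")
}

#' @export
print.CellGraph <- function(x, ...) {
  cat(sprintf("CellGraph: %d cells, metric = %s, %d positive edges\n",
              nrow(x$weights), x$metric,
              sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Split cells into core and non-core by edge-weight thresholding
#'
#' Sorts all `m(m-1)/2` edge weights of the full similarity graph in
#' decreasing order and retains the strongest `ceiling(edge_fraction * E)`
#' edges, together with every edge tied with the weight of the last one
#' retained. Cells incident to at least one retained edge are *core cells* —
#' tightly connected to their neighbours and presumed to lie near cluster
#' centers; the rest are *non-core cells*, presumed to sit in cluster
#' boundary regions, and are clustered only in the second step
#' ([assign_noncore()]). Retained edges of weight exactly 0 are treated as
#' absent, so every core cell has strictly positive degree in the core graph.
#'
#' Two safeguards demote cells that technically touch a retained edge but are
#' not "closely connected" in any meaningful sense — left in place, either
#' kind masquerades as a cluster of its own during the agglomeration (its
#' merge into the rest is enormously expensive, which hijacks the automatic
#' selection of the cluster count):
#' * cells with fewer retained edges than `min_degree_fraction` times the
#'   median retained-edge count of the provisional core (stray cells hanging
#'   off the graph by one or two marginal edges);
#' * connected components of the thresholded graph smaller than
#'   `min_component_size` (isolated islets of mutually similar strays).
#'
#' @param g A `CellGraph` from [pairwise_similarity()].
#' @param edge_fraction Fraction of edges to retain, in `(0, 1]`. Default
#'   0.25, which keeps roughly the strongest quarter of the graph.
#' @param min_degree_fraction Demote provisional core cells whose retained
#'   edge count is below this fraction of the median (default 0.1). In small
#'   sparse graphs the median itself is small and the rule is inert.
#' @param min_component_size Smallest connected component of the thresholded
#'   graph that still counts as core (default 3). If no component reaches
#'   this size, the largest one is kept with a warning.
#' @return A list with `graph` (the core-cell `CellGraph`, non-retained edges
#'   zeroed) and `split` (class `CoreSplit`: `core_cell_ids`,
#'   `noncore_cell_ids`, `s_c` threshold, `retained_edge_count`,
#'   `edge_fraction`).
#' @export
select_core_cells <- function(g, edge_fraction = 0.25,
                              min_degree_fraction = 0.1,
                              min_component_size = 3) {
  stopifnot(inherits(g, "CellGraph"))
  if (edge_fraction <= 0 || edge_fraction > 1)
    stop("edge_fraction must be in (0, 1]")
  w <- g$weights
  up <- upper.tri(w)
  ew <- w[up]
  n_edges <- length(ew)
  n_keep <- ceiling(edge_fraction * n_edges)
  sorted <- sort(ew, decreasing = TRUE)
  s_c <- sorted[n_keep]
  if (sorted[1] == sorted[n_edges])
    warning("all edge weights equal; every edge retained")
  keep <- w >= s_c & w > 0
  diag(keep) <- FALSE
  w_cc <- w
  w_cc[!keep] <- 0
  core <- which(rowSums(keep) > 0)
  retained_at_threshold <- sum(keep[up])
  if (length(core) > 1L) {
    # stray cells: far fewer retained edges than the typical core cell
    ecount <- rowSums(keep[core, core, drop = FALSE])
    core <- core[ecount >= min_degree_fraction * stats::median(ecount)]
    # demotion may strand neighbours of demoted cells; peel until stable
    repeat {
      ecount <- rowSums(keep[core, core, drop = FALSE])
      if (all(ecount > 0) || length(core) == 0L) break
      core <- core[ecount > 0]
    }
  }
  if (length(core)) {
    comp <- .graph_components(keep[core, core, drop = FALSE])
    sizes <- tabulate(comp)
    big <- sizes >= min_component_size
    if (!any(big)) {
      warning("no core component reaches min_component_size; keeping the largest")
      big <- sizes == max(sizes)
    }
    core <- core[comp %in% which(big)]
  }
  keep[-core, ] <- FALSE
  keep[, -core] <- FALSE
  w_cc[!keep] <- 0
  noncore <- setdiff(seq_len(nrow(w)), core)
  graph_cc <- structure(list(weights = w_cc[core, core, drop = FALSE],
                             metric = g$metric, snn_k = g$snn_k),
                        class = "CellGraph")
  split <- structure(list(core_cell_ids = rownames(w)[core],
                          noncore_cell_ids = rownames(w)[noncore],
                          s_c = s_c,
                          retained_edge_count = retained_at_threshold,
                          edge_fraction = edge_fraction),
                     class = "CoreSplit")
  list(graph = graph_cc, split = split)
}

# Connected-component labels of a logical adjacency matrix (BFS).
.graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(.adjacent_any(adj, frontier))
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

# column indices adjacent to any row in `rows`
.adjacent_any <- function(adj, rows) {
  if (length(rows) == 1L) adj[rows, ] else colSums(adj[rows, , drop = FALSE]) > 0
}

#' @export
print.CoreSplit <- function(x, ...) {
  cat(sprintf("CoreSplit: %d core / %d non-core cells (threshold s_c = %.4f, %d edges retained)\n",
              length(x$core_cell_ids), length(x$noncore_cell_ids),
              x$s_c, x$retained_edge_count))
  invisible(x)
}
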
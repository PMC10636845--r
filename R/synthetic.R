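#' Simulate an scRNA-seq-like expression matrix with planted clusters
#'
#' Generates a nonnegative cells x genes matrix mimicking the features of
#' single-cell expression data that drive the pipeline: right- or
#' non-right-skewed gene scales, planted cluster structure carried by
#' disjoint marker-gene sets, optional boundary cells placed midway between
#' cluster centroids (emulating the hard-to-cluster non-core population),
#' and Bernoulli dropout zeros.
#'
#' Each gene gets a base mean: lognormal(meanlog = 1, sdlog = 2.25) under
#' `skew_mode = "heavy_tail"` (heavy right tail; the right-skewness
#' coefficient of such matrices falls in the log-transform regime) or
#' gamma(shape = 50, rate = 10) under `"uniform"` (tight, near-symmetric
#' maxima; RSC stays well below the transform threshold). Each cluster
#' shifts its own 10% block of marker genes upward so that the Euclidean
#' distance between any two cluster centroids equals `separation` noise
#' standard deviations. Cell profiles are the centroid plus Gaussian noise
#' (sd 1), truncated at zero.
#'
#' A `boundary_fraction` of cells is instead placed between two randomly
#' chosen centroids — at a uniform interpolation point near the midpoint
#' (mixing weight 0.4–0.6) with inflated noise (2 x sd), emulating
#' transitional cells that sit in cluster boundary regions without forming
#' tight artificial subclusters of their own. Each carries the label of its
#' nearer parent centroid; these cells are genuinely ambiguous, as real
#' boundary cells are.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param k_true Number of planted clusters (each is guaranteed nonempty).
#' @param separation Centroid spacing in noise-SD units. Values >= 6 give
#'   essentially separable clusters.
#' @param boundary_fraction Fraction of cells drawn at centroid midpoints.
#' @param skew_mode `"heavy_tail"` or `"uniform"`.
#' @param dropout_rate Probability that an entry is zeroed, in `[0, 1)`.
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#'   The caller's RNG state is left untouched.
#' @return A list with `x` (an `ExpressionMatrix`), `labels` (integer vector
#'   in `1..k_true`, named by cell id) and `is_boundary` (logical vector).
#' @export
simulate_cells <- function(n_cells = 300, n_genes = 200, k_true = 3,
                           separation = 8, boundary_fraction = 0,
                           skew_mode = c("heavy_tail", "uniform"),
                           dropout_rate = 0, seed = 1) {
  skew_mode <- match.arg(skew_mode)
  if (k_true > n_cells) stop("k_true exceeds n_cells")
  if (k_true < 1L) stop("k_true must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (boundary_fraction < 0 || boundary_fraction > 1)
    stop("boundary_fraction must be in [0, 1]")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  base <- switch(skew_mode,
                 heavy_tail = stats::rlnorm(n_genes, meanlog = 1, sdlog = 2.25),
                 uniform = stats::rgamma(n_genes, shape = 50, rate = 10))
  noise_sd <- 1
  n_marker <- max(1L, floor(n_genes / (10L * k_true)) * 1L)
  n_marker <- min(n_marker, n_genes %/% k_true)
  shift <- separation * noise_sd / sqrt(2 * n_marker)
  centroids <- matrix(rep(base, each = k_true), k_true, n_genes)
  for (k in seq_len(k_true)) {
    markers <- seq.int((k - 1L) * n_marker + 1L, k * n_marker)
    centroids[k, markers] <- centroids[k, markers] + shift
  }

  labels <- sample(rep_len(seq_len(k_true), n_cells))
  n_boundary <- round(boundary_fraction * n_cells)
  is_boundary <- rep(FALSE, n_cells)
  mu <- centroids[labels, , drop = FALSE]
  cell_sd <- rep(noise_sd, n_cells)
  if (n_boundary > 0 && k_true >= 2L) {
    bidx <- sample(n_cells, n_boundary)
    is_boundary[bidx] <- TRUE
    for (i in bidx) {
      pair <- sample(k_true, 2L)
      alpha <- stats::runif(1, 0.4, 0.6)
      mu[i, ] <- (1 - alpha) * centroids[pair[1L], ] + alpha * centroids[pair[2L], ]
      labels[i] <- if (alpha < 0.5) pair[1L] else pair[2L]
      cell_sd[i] <- 2 * noise_sd
    }
  }

  vals <- mu + matrix(stats::rnorm(n_cells * n_genes), n_cells, n_genes) * cell_sd
  vals <- pmax(vals, 0)
  if (dropout_rate > 0) {
    drop <- matrix(stats::runif(n_cells * n_genes) < dropout_rate,
                   n_cells, n_genes)
    vals[drop] <- 0
  }
  ids <- sprintf("cell_%03d", seq_len(n_cells))
  x <- expression_matrix(vals, cell_ids = ids,
                         gene_ids = sprintf("gene_%04d", seq_len(n_genes)))
  list(x = x, labels = stats::setNames(labels, ids), is_boundary = is_boundary)
}

#' Write a simulated dataset to disk
#'
#' Writes the matrix as a genes-in-rows TSV (readable by
#' [read_expression()]) and the planted labels as a two-column TSV.
#'
#' @param sim Result of [simulate_cells()].
#' @param matrix_path,labels_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_simulation <- function(sim, matrix_path, labels_path) {
  m <- t(sim$x$values)
  dt <- data.table::data.table(gene = rownames(m))
  for (j in seq_len(ncol(m))) dt[[colnames(m)[j]]] <- m[, j]
  data.table::fwrite(dt, matrix_path, sep = "\t")
  data.table::fwrite(data.table::data.table(cell = names(sim$labels),
                                            label = unname(sim$labels)),
                     labels_path, sep = "\t")
  invisible(c(matrix_path, labels_path))
}
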
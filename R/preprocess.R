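#' Remove genes detected in too few cells
#'
#' Genes whose expression is dominated by zeros carry little clustering
#' signal. A gene is kept when it is detected (value > 0) in at least
#' `min_fraction` of cells; the boundary is inclusive, so a gene detected in
#' exactly `min_fraction` of cells survives.
#'
#' @param x An `ExpressionMatrix` on the linear (non-log) scale.
#' @param min_fraction Minimum detected fraction of cells, in `[0, 1]`.
#'   Default 0.02.
#' @return An `ExpressionMatrix` with the surviving genes, order preserved.
#' @export
filter_low_expressed_genes <- function(x, min_fraction = 0.02) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$log_transformed) stop("gene filtering expects a non-log-transformed matrix")
  if (min_fraction < 0 || min_fraction > 1) stop("min_fraction must be in [0, 1]")
  if (nrow(x$values) == 0L || ncol(x$values) == 0L) stop("empty input")
  detected <- colMeans(x$values > 0)
  keep <- detected >= min_fraction
  if (!any(keep)) stop("no genes survive filter")
  expression_matrix(x$values[, keep, drop = FALSE],
                    log_transformed = x$log_transformed)
}

#' Right-skewness coefficient of gene maxima
#'
#' Measures how right-skewed the per-gene maximum expression values are.
#' Writing \eqn{g_i^{max}} for gene i's maximum over cells, genes whose maxima
#' fall outside \eqn{[Q1 - 1.5\,IQR,\; Q3 + 1.5\,IQR]} are set aside as
#' outliers; on the retained maxima, with mean \eqn{\mu} and \eqn{l} the number
#' of maxima at or above \eqn{\mu},
#' \deqn{RSC = \frac{\sum_{g_i^{max} \ge \mu} (g_i^{max} - \mu)}{l\,\mu},}
#' the average positive deviation above the mean, relative to the mean. Large
#' values indicate a heavy right tail, in which case a log transformation
#' before similarity computation is advisable (see [maybe_log_transform()]).
#'
#' Quartiles use the interpolated order-statistic convention
#' (`stats::quantile` type 7); the convention is recorded in the report.
#'
#' @param x An `ExpressionMatrix` with at least 2 genes.
#' @return A list of class `RSCReport`: `rsc`, `mu`, `l`,
#'   `n_outlier_genes_removed`, `q1`, `q3`, `quartile_type`, `log_applied`
#'   (filled in by [maybe_log_transform()]).
#' @export
compute_rsc <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 2L) stop("need at least 2 genes to compute RSC")
  gmax <- apply(x$values, 2L, max)
  q <- stats::quantile(gmax, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  keep <- gmax >= q[1] - 1.5 * iqr & gmax <= q[2] + 1.5 * iqr
  retained <- gmax[keep]
  if (length(retained) < 2L) stop("fewer than 2 genes retained after outlier removal")
  mu <- mean(retained)
  if (mu == 0) stop("degenerate matrix, RSC undefined")
  upper <- retained[retained >= mu]
  l <- length(upper)
  rsc <- sum(upper - mu) / (l * mu)
  structure(list(rsc = rsc, mu = mu, l = l,
                 n_outlier_genes_removed = sum(!keep),
                 q1 = q[1], q3 = q[2], quartile_type = 7L,
                 log_applied = NA),
            class = "RSCReport")
}

#' @export
print.RSCReport <- function(x, ...) {
  cat(sprintf("RSC = %.4f (mu = %.3f, l = %d, %d outlier genes excluded)\n",
              x$rsc, x$mu, x$l, x$n_outlier_genes_removed))
  if (!is.na(x$log_applied))
    cat(sprintf("log2(x + 1) transformation %s\n",
                if (x$log_applied) "applied" else "not applied"))
  invisible(x)
}

#' Log-transform an expression matrix when its gene maxima are right-skewed
#'
#' Computes the right-skewness coefficient ([compute_rsc()]) and, when it
#' exceeds `rsc_threshold`, replaces every value v by `log2(v + 1)`. Matrices
#' that are not right-skewed are returned unchanged: log-transforming such
#' data distorts between-gene differences rather than taming them.
#'
#' @param x An `ExpressionMatrix`, not yet log-transformed.
#' @param rsc_threshold Transform when RSC exceeds this value. Default 0.8.
#' @param force `"auto"` (decide by RSC), `"on"` (always transform) or
#'   `"off"` (never transform); RSC is still computed and reported.
#' @return A list with elements `x` (the possibly transformed
#'   `ExpressionMatrix`) and `report` (the `RSCReport`, with `log_applied`
#'   filled in).
#' @export
maybe_log_transform <- function(x, rsc_threshold = 0.8,
                                force = c("auto", "on", "off")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  force <- match.arg(force)
  if (x$log_transformed) stop("matrix is already log-transformed")
  report <- compute_rsc(x)
  apply_log <- switch(force,
                      auto = report$rsc > rsc_threshold,
                      on = TRUE,
                      off = FALSE)
  report$log_applied <- apply_log
  if (apply_log) {
    x <- expression_matrix(log2(x$values + 1), log_transformed = TRUE)
  }
  list(x = x, report = report)
}
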
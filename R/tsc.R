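#' Two-step clustering of an expression matrix
#'
#' Runs the full pipeline: (1) gene filtering and the right-skewness-driven
#' log-transform decision; (2) cell-similarity graph construction and
#' core/non-core splitting by edge-weight thresholding; (3) t-step random
#' walk on the core graph and the degree-weighted walk distance; (4)
#' Ward-style agglomeration of the core cells with automatic selection of
#' the number of clusters; (5) nearest-center assignment of the non-core
#' cells in expression space.
#'
#' In `one_step = TRUE` mode the core/non-core split is disabled
#' (`edge_fraction` is forced to 1) and every cell is clustered directly by
#' the same machinery — the ablation baseline against which the two-step
#' strategy is compared.
#'
#' @param x An `ExpressionMatrix` (raw scale unless already log-transformed).
#' @param metric Cell-similarity metric; see [pairwise_similarity()].
#' @param edge_fraction Fraction of graph edges retained when selecting core
#'   cells; see [select_core_cells()].
#' @param walk_steps Random-walk length t; see [walk_probabilities()].
#' @param snn_k Neighbourhood size for the SNN metric.
#' @param min_expressed_fraction Gene-filter threshold; see
#'   [filter_low_expressed_genes()]. Set to 0 to skip filtering.
#' @param rsc_threshold Log-transform when RSC exceeds this;
#'   see [maybe_log_transform()].
#' @param force_log `"auto"`, `"on"` or `"off"`.
#' @param k Fixed number of clusters; `NULL` (default) selects K
#'   automatically via [select_k()].
#' @param k_min,k_max Search range for the automatic K selection.
#' @param mode Cell-to-cluster distance mode for the agglomeration;
#'   see [cluster_cell_distance()].
#' @param assign_metric Distance for non-core assignment;
#'   see [assign_noncore()].
#' @param one_step Logical; run the one-step ablation (no core/non-core
#'   split).
#' @param verbose Logical; log per-stage progress and timings.
#' @return An object of class `TSCResult`: `labels` (integer cluster label
#'   per input cell, input order), `k`, `is_core` (logical per cell),
#'   `centers` (K x genes matrix), `rsc_report`, `core_split`, `state` (the
#'   `ClusterState`), and `config` (the effective parameters).
#' @export
#'
#' @examples
#' sim <- simulate_cells(n_cells = 60, n_genes = 100, k_true = 3, seed = 7)
#' res <- run_tsc(sim$x)
#' table(res$labels, sim$labels)
run_tsc <- function(x,
                    metric = c("pcc", "scc", "ed", "md", "snn"),
                    edge_fraction = 0.25,
                    walk_steps = 4,
                    snn_k = 20,
                    min_expressed_fraction = 0.02,
                    rsc_threshold = 0.8,
                    force_log = c("auto", "on", "off"),
                    k = NULL,
                    k_min = 2,
                    k_max = NULL,
                    mode = c("walktrap", "literal"),
                    assign_metric = c("euclidean", "pcc"),
                    one_step = FALSE,
                    verbose = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  metric <- match.arg(metric)
  force_log <- match.arg(force_log)
  mode <- match.arg(mode)
  assign_metric <- match.arg(assign_metric)
  if (one_step) edge_fraction <- 1
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stamp <- function() proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage, t0) {
    timings[[stage]] <<- stamp() - t0
  }

  t0 <- stamp()
  rsc_report <- NULL
  if (!x$log_transformed) {
    if (min_expressed_fraction > 0)
      x <- filter_low_expressed_genes(x, min_expressed_fraction)
    pre <- maybe_log_transform(x, rsc_threshold, force = force_log)
    x <- pre$x
    rsc_report <- pre$report
    say("preprocess", "RSC = %.3f, log %s; %d genes retained",
        rsc_report$rsc, if (rsc_report$log_applied) "applied" else "skipped",
        ncol(x$values))
  }
  tick("preprocess", t0)

  t0 <- stamp()
  g <- pairwise_similarity(x, metric, snn_k = snn_k)
  cs <- select_core_cells(g, edge_fraction)
  say("cellgraph", "%d core / %d non-core cells (s_c = %.4f)",
      length(cs$split$core_cell_ids), length(cs$split$noncore_cell_ids),
      cs$split$s_c)
  tick("cellgraph", t0)
  if (length(cs$split$core_cell_ids) < 2L)
    stop("cellgraph stage: fewer than 2 core cells; lower edge_fraction?")

  t0 <- stamp()
  wp <- walk_probabilities(cs$graph, t = walk_steps)
  tick("randomwalk", t0)

  t0 <- stamp()
  state <- agglomerate(wp, mode = mode)
  kk <- if (is.null(k)) select_k(state, k_min = k_min, k_max = k_max)
        else as.integer(k)
  kk <- min(kk, state$n)
  core_labels <- cut_clusters(state, kk)
  say("agglomerate", "K = %d", kk)
  tick("agglomerate", t0)

  t0 <- stamp()
  centers <- compute_centers(x, core_labels)
  noncore_labels <- assign_noncore(x, centers, cs$split$noncore_cell_ids,
                                   method = assign_metric)
  tick("assign", t0)

  all_ids <- cell_ids(x)
  labels <- stats::setNames(integer(length(all_ids)), all_ids)
  labels[names(core_labels)] <- core_labels
  labels[names(noncore_labels)] <- noncore_labels
  is_core <- stats::setNames(all_ids %in% cs$split$core_cell_ids, all_ids)
  if (verbose)
    say("done", "timings (s): %s",
        paste(sprintf("%s %.2f", names(timings), unlist(timings)), collapse = ", "))

  structure(list(labels = labels, k = kk, is_core = is_core,
                 centers = centers, rsc_report = rsc_report,
                 core_split = cs$split, state = state,
                 config = list(metric = metric, edge_fraction = edge_fraction,
                               walk_steps = walk_steps, snn_k = snn_k,
                               min_expressed_fraction = min_expressed_fraction,
                               rsc_threshold = rsc_threshold,
                               force_log = force_log, k = k, k_min = k_min,
                               k_max = k_max, mode = mode,
                               assign_metric = assign_metric,
                               one_step = one_step),
                 timings = timings),
            class = "TSCResult")
}

#' @export
print.TSCResult <- function(x, ...) {
  cat(sprintf("TSCResult: %d cells in %d clusters (%d core, %d non-core)\n",
              length(x$labels), x$k, sum(x$is_core), sum(!x$is_core)))
  if (!is.null(x$rsc_report))
    cat(sprintf("  RSC = %.3f, log2(x+1) %s\n", x$rsc_report$rsc,
                if (x$rsc_report$log_applied) "applied" else "not applied"))
  cat(sprintf("  metric = %s, edge_fraction = %g, t = %d\n",
              x$config$metric, x$config$edge_fraction, x$config$walk_steps))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = " "), "\n")
  invisible(x)
}

#' Write a clustering result to disk
#'
#' Writes the per-cell label table (`cell_id`, `cluster`, `is_core`) and the
#' cluster-center matrix as TSV, and the run metadata (metric, walk steps,
#' edge fraction, RSC, chosen K) as JSON.
#'
#' @param res A `TSCResult`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix, default `"tsc"`.
#' @return Invisibly, the paths written.
#' @export
write_tsc_result <- function(res, dir, prefix = "tsc") {
  stopifnot(inherits(res, "TSCResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab_path <- file.path(dir, paste0(prefix, "_labels.tsv"))
  cen_path <- file.path(dir, paste0(prefix, "_centers.tsv"))
  meta_path <- file.path(dir, paste0(prefix, "_meta.json"))
  data.table::fwrite(
    data.table::data.table(cell_id = names(res$labels),
                           cluster = unname(res$labels),
                           is_core = unname(res$is_core)),
    lab_path, sep = "\t")
  cen <- data.table::data.table(cluster = rownames(res$centers))
  for (j in seq_len(ncol(res$centers)))
    cen[[colnames(res$centers)[j]]] <- res$centers[, j]
  data.table::fwrite(cen, cen_path, sep = "\t")
  meta <- c(res$config,
            list(k_selected = res$k,
                 n_core = sum(res$is_core),
                 n_noncore = sum(!res$is_core),
                 rsc = if (is.null(res$rsc_report)) NA else res$rsc_report$rsc,
                 log_applied = if (is.null(res$rsc_report)) NA
                               else res$rsc_report$log_applied,
                 nmi_normalization = "arithmetic"))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(lab_path, cen_path, meta_path))
}

#' Sweep the random-walk length on a fixed similarity graph
#'
#' Recomputes the clustering for each walk length `t`, reusing the
#' preprocessing and the similarity graph, and reports the selected K (and
#' the adjusted Rand index against reference labels, when provided). Useful
#' for checking the method's stability in t.
#'
#' @param x An `ExpressionMatrix`.
#' @param t_values Integer vector of walk lengths to try.
#' @param labels_true Optional reference labels (named by cell id or in
#'   input cell order).
#' @param ... Further arguments passed to the pipeline stages:
#'   `metric`, `edge_fraction`, `snn_k`, `min_expressed_fraction`,
#'   `rsc_threshold`, `force_log`, `k`, `k_min`, `k_max`, `mode`,
#'   `assign_metric` (same defaults as [run_tsc()]).
#' @return A data.frame with columns `t`, `k` and, when `labels_true` is
#'   given, `ari`.
#' @export
sweep_walk_steps <- function(x, t_values = 2:15, labels_true = NULL, ...) {
  args <- list(...)
  take <- function(name, default) if (name %in% names(args)) args[[name]] else default
  metric <- take("metric", "pcc")
  edge_fraction <- take("edge_fraction", 0.25)
  snn_k <- take("snn_k", 20)
  min_expressed_fraction <- take("min_expressed_fraction", 0.02)
  rsc_threshold <- take("rsc_threshold", 0.8)
  force_log <- take("force_log", "auto")
  fixed_k <- take("k", NULL)
  k_min <- take("k_min", 2)
  k_max <- take("k_max", NULL)
  mode <- take("mode", "walktrap")
  assign_metric <- take("assign_metric", "euclidean")

  if (!x$log_transformed) {
    if (min_expressed_fraction > 0)
      x <- filter_low_expressed_genes(x, min_expressed_fraction)
    x <- maybe_log_transform(x, rsc_threshold, force = force_log)$x
  }
  g <- pairwise_similarity(x, metric, snn_k = snn_k)
  cs <- select_core_cells(g, edge_fraction)
  out <- lapply(t_values, function(t) {
    wp <- walk_probabilities(cs$graph, t = t)
    state <- agglomerate(wp, mode = mode)
    kk <- if (is.null(fixed_k)) select_k(state, k_min = k_min, k_max = k_max)
          else as.integer(fixed_k)
    kk <- min(kk, state$n)
    core_labels <- cut_clusters(state, kk)
    centers <- compute_centers(x, core_labels)
    noncore_labels <- assign_noncore(x, centers, cs$split$noncore_cell_ids,
                                     method = assign_metric)
    labels <- stats::setNames(integer(nrow(x$values)), cell_ids(x))
    labels[names(core_labels)] <- core_labels
    labels[names(noncore_labels)] <- noncore_labels
    row <- data.frame(t = t, k = kk)
    if (!is.null(labels_true)) {
      truth <- if (!is.null(names(labels_true)))
        labels_true[names(labels)] else labels_true
      row$ari <- adjusted_rand_index(truth, labels)
    }
    row
  })
  do.call(rbind, out)
}
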
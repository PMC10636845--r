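#' Construct an expression matrix object
#'
#' The package's primary input container: a dense cells x genes matrix of
#' nonnegative expression values (FPKM, CPM, UMI counts or similar) together
#' with unique cell and gene identifiers and a flag recording whether the
#' values have already been log-transformed.
#'
#' @param values Numeric matrix, cells in rows and genes in columns. Row and
#'   column names, when present, seed `cell_ids` / `gene_ids`.
#' @param cell_ids Character vector of unique cell identifiers (length
#'   `nrow(values)`). Defaults to row names, or `cell_1 ... cell_m`.
#' @param gene_ids Character vector of unique gene identifiers (length
#'   `ncol(values)`). Defaults to column names, or `gene_1 ... gene_p`.
#' @param log_transformed Logical; `TRUE` when `values` are already on the
#'   log scale (negative entries are then permitted).
#'
#' @return An object of class `ExpressionMatrix`.
#' @export
#'
#' @examples
#' x <- expression_matrix(matrix(rpois(20, 5), nrow = 4))
#' dim(x)
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL,
                              log_transformed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids))
      cell_ids <- paste0("cell_", seq_len(nrow(values)), recycle0 = TRUE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids))
      gene_ids <- paste0("gene_", seq_len(ncol(values)), recycle0 = TRUE)
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length (", length(cell_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length (", length(gene_ids), ") != number of columns (",
         ncol(values), ")")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyNA(values)) stop("expression values contain NA")
  if (!log_transformed && any(values < 0))
    stop("negative expression values in a non-log-transformed matrix")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, log_transformed = isTRUE(log_transformed)),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) x$values

#' Cell and gene identifiers of an expression matrix
#'
#' @param x An `ExpressionMatrix`.
#' @return Character vector of identifiers.
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log_transformed) "log" else "linear"))
  invisible(x)
}

#' Read a dense expression table
#'
#' Reads a CSV/TSV expression table with one header row and one leading label
#' column. Expression tables conventionally store genes in rows and cells in
#' columns; set `orientation = "cells"` for tables already in cells x genes
#' layout.
#'
#' @param path Path to a delimited text file. The delimiter is auto-detected
#'   by [data.table::fread()].
#' @param orientation `"genes"` (default; genes in rows, cells in columns) or
#'   `"cells"` (cells in rows).
#' @return An `ExpressionMatrix` (cells x genes).
#' @export
read_expression <- function(path, orientation = c("genes", "cells")) {
  orientation <- match.arg(orientation)
  dt <- data.table::fread(path, header = TRUE)
  labels <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (orientation == "genes") {
    expression_matrix(t(m), cell_ids = colnames(m), gene_ids = labels)
  } else {
    expression_matrix(m, cell_ids = labels, gene_ids = colnames(m))
  }
}

#' Read a sparse MatrixMarket expression matrix
#'
#' Reads an MTX triplet file plus sidecar row and column label files (one
#' label per line, as written by common scRNA-seq pipelines).
#'
#' @param mtx_path Path to the MatrixMarket file.
#' @param row_ids_path,col_ids_path Paths to plain-text label files for the
#'   MTX rows and columns respectively.
#' @param orientation `"genes"` when MTX rows are genes (the common
#'   convention), `"cells"` when they are cells.
#' @return An `ExpressionMatrix` (cells x genes, densified).
#' @export
read_expression_mtx <- function(mtx_path, row_ids_path, col_ids_path,
                                orientation = c("genes", "cells")) {
  orientation <- match.arg(orientation)
  m <- as.matrix(Matrix::readMM(mtx_path))
  row_ids <- readLines(row_ids_path)
  col_ids <- readLines(col_ids_path)
  if (length(row_ids) != nrow(m))
    stop("row label file has ", length(row_ids), " entries for ", nrow(m), " rows")
  if (length(col_ids) != ncol(m))
    stop("column label file has ", length(col_ids), " entries for ", ncol(m), " columns")
  if (orientation == "genes") {
    expression_matrix(t(m), cell_ids = col_ids, gene_ids = row_ids)
  } else {
    expression_matrix(m, cell_ids = row_ids, gene_ids = col_ids)
  }
}
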
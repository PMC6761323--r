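#' Describe the layout of a dense delimited expression dump
#'
#' Single-cell repositories commonly distribute genes x cells tables as
#' delimited text with a few leading metadata rows (cell ids, labels,
#' totals, ...) before the numeric block -- the CEF-style dump. A dialect
#' records where everything sits so [read_dense()] can parse such a file.
#' All indices are 1-based.
#'
#' @param delimiter field separator, default TAB.
#' @param meta_rows number of leading metadata rows before the data block.
#' @param label_row which metadata row (1..`meta_rows`) carries the per-cell
#'   label, or `NA` if labels come from a separate file.
#' @param id_row which metadata row carries the cell identifiers; default 1.
#' @param gene_col column holding gene symbols (default 1).
#' @param first_data_col first column of numeric data (default
#'   `gene_col + 1`).
#' @return A list of class `"dense_dialect"`.
#' @export
dense_dialect <- function(delimiter = "\t", meta_rows = 1L, label_row = 1L,
                          id_row = 1L, gene_col = 1L,
                          first_data_col = gene_col + 1L) {
  if (!is.na(label_row) && (label_row < 1 || label_row > meta_rows))
    stop("label_row must lie in 1..meta_rows or be NA")
  if (id_row < 1 || id_row > meta_rows)
    stop("id_row must lie in 1..meta_rows")
  structure(list(delimiter = delimiter, meta_rows = as.integer(meta_rows),
                 label_row = if (is.na(label_row)) NA_integer_ else as.integer(label_row),
                 id_row = as.integer(id_row),
                 gene_col = as.integer(gene_col),
                 first_data_col = as.integer(first_data_col)),
            class = "dense_dialect")
}

#' Read a dense delimited expression matrix
#'
#' Parses a genes x cells text dump laid out as described by a
#' [dense_dialect()]. Ragged rows, non-numeric data cells, and negative
#' values are hard errors with the offending 1-based coordinate in the
#' message; silent coercion would corrupt downstream statistics.
#'
#' @param path file path.
#' @param dialect a [dense_dialect()].
#' @param labels optional character vector of per-cell labels, used when the
#'   dialect declares no label row (and overriding it when both are given).
#' @return An [expression_matrix()].
#' @export
read_dense <- function(path, dialect = dense_dialect(), labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(inherits(dialect, "dense_dialect"))
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > dialect$meta_rows & lines == "")]
  if (length(lines) <= dialect$meta_rows)
    stop("file has no data rows: ", path)
  fields <- strsplit(lines, dialect$delimiter, fixed = TRUE)
  width <- length(fields[[1]])
  bad <- which(vapply(fields, length, 1L) != width)
  if (length(bad))
    stop("ragged row: line ", bad[1], " has ", length(fields[[bad[1]]]),
         " fields, expected ", width)
  n_cells <- width - dialect$first_data_col + 1L
  if (n_cells < 1) stop("no data columns after column ", dialect$first_data_col - 1L)
  meta <- fields[seq_len(dialect$meta_rows)]
  cell_cols <- seq.int(dialect$first_data_col, width)
  cell_ids <- meta[[dialect$id_row]][cell_cols]
  if (is.null(labels)) {
    if (is.na(dialect$label_row))
      stop("dialect declares no label row and no labels were supplied")
    labels <- meta[[dialect$label_row]][cell_cols]
  }
  if (length(labels) != n_cells)
    stop("expected ", n_cells, " labels, got ", length(labels))
  data <- fields[-seq_len(dialect$meta_rows)]
  gene_symbols <- vapply(data, `[`, "", dialect$gene_col)
  vals <- vapply(data, function(f) {
    suppressWarnings(as.numeric(f[cell_cols]))
  }, numeric(n_cells))
  # vapply returns cells x genes; transpose back
  vals <- if (n_cells == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric data cell at line ", dialect$meta_rows + idx[1],
         ", column ", dialect$first_data_col + idx[2] - 1L)
  }
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value at line ", dialect$meta_rows + idx[1],
         ", column ", dialect$first_data_col + idx[2] - 1L)
  }
  expression_matrix(vals, gene_symbols, cell_ids, labels)
}

#' Write an expression matrix in the dense dialect
#'
#' Inverse of [read_dense()] for the default single-metadata-row layout
#' plus an optional label row; used by the `simulate` driver and in
#' round-trip tests.
#'
#' @param x an [expression_matrix()].
#' @param path output file path.
#' @param delimiter field separator.
#' @return `path`, invisibly. The file has two metadata rows (cell ids,
#'   labels) readable with `dense_dialect(meta_rows = 2, label_row = 2)`.
#' @export
write_dense <- function(x, path, delimiter = "\t") {
  stopifnot(inherits(x, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  put <- function(...) writeLines(paste(c(...), collapse = delimiter), con)
  put("cell_id", x$cell_ids)
  put("label", as.character(x$labels))
  vals <- format(x$values, trim = TRUE, scientific = FALSE, digits = 15)
  for (i in seq_len(nrow(vals))) put(x$gene_symbols[i], vals[i, ])
  invisible(path)
}

#' Read an expression matrix from Matrix Market triplets
#'
#' Reads a sparse genes x cells matrix in Matrix Market coordinate format
#' (1-based indices per that standard) with companion one-entry-per-line
#' files for gene symbols, cell ids, and cell labels, and densifies it.
#' The result is identical to reading the equivalent dense dump.
#'
#' @param matrix_path Matrix Market coordinate file.
#' @param genes_path text file, one gene symbol per line (rows).
#' @param cells_path text file, one cell id per line (columns).
#' @param labels_path text file, one label per line, aligned with
#'   `cells_path`.
#' @return An [expression_matrix()].
#' @export
read_sparse_triplets <- function(matrix_path, genes_path, cells_path,
                                 labels_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  labels <- readLines(labels_path)
  if (nrow(m) != length(genes))
    stop("matrix has ", nrow(m), " rows but ", length(genes),
         " gene symbols were supplied")
  if (ncol(m) != length(cells))
    stop("matrix has ", ncol(m), " columns but ", length(cells),
         " cell ids were supplied")
  if (length(labels) != length(cells))
    stop("cell id and label files differ in length (", length(cells),
         " vs ", length(labels), ")")
  expression_matrix(as.matrix(m), genes, cells, labels)
}
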
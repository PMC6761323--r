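#' Construct an expression matrix with cell labels
#'
#' The basic data container: a nonnegative genes x cells matrix of
#' expression values (molecule counts or comparable), together with gene
#' symbols, cell identifiers, and one categorical label per cell (a time
#' point, a cell type, a treatment group, ...). The label is the metadata
#' the downstream singular-vector selection regresses against, so at least
#' two distinct levels must be present.
#'
#' @param values numeric matrix, genes on rows, cells on columns; all
#'   entries finite and >= 0.
#' @param gene_symbols character vector, one symbol per row.
#' @param cell_ids character vector, one identifier per column.
#' @param labels vector coercible to factor, one label per cell. Missing or
#'   empty labels are kept and assigned the literal level `"unknown"`.
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `values`, `gene_symbols`, `cell_ids`, `labels` (a factor).
#' @examples
#' m <- expression_matrix(matrix(0:5, 2, 3), c("A", "B"),
#'                        paste0("c", 1:3), c("t1", "t1", "t2"))
#' dim(m$values)
#' @export
expression_matrix <- function(values, gene_symbols, cell_ids, labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_symbols <- as.character(gene_symbols)
  cell_ids <- as.character(cell_ids)
  labels <- as.character(labels)
  labels[is.na(labels) | labels == ""] <- "unknown"
  if (nrow(values) != length(gene_symbols))
    stop("row count (", nrow(values), ") does not match number of gene symbols (",
         length(gene_symbols), ")")
  if (ncol(values) != length(cell_ids))
    stop("column count (", ncol(values), ") does not match number of cell ids (",
         length(cell_ids), ")")
  if (ncol(values) != length(labels))
    stop("column count (", ncol(values), ") does not match number of labels (",
         length(labels), ")")
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (any(values < 0))
    stop("expression values must be nonnegative")
  if (length(unique(labels)) < 2)
    stop("at least 2 distinct cell labels are required, got ",
         length(unique(labels)))
  dimnames(values) <- list(gene_symbols, cell_ids)
  structure(
    list(values = values, gene_symbols = gene_symbols,
         cell_ids = cell_ids, labels = factor(labels)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " cells, ", nlevels(x$labels), " label levels (",
      paste(levels(x$labels), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Pair two expression matrices on their common genes
#'
#' Restricts two expression matrices to the gene symbols they share and
#' aligns both on the same sorted symbol order, producing the paired input
#' the cross-product decomposition consumes. Matching is exact-string by
#' default; `case_insensitive = TRUE` upper-cases symbols before matching,
#' which is the usual convention when pairing human (upper-case) with mouse
#' (title-case) symbols. Duplicate symbols within one matrix are either
#' summed row-wise (`"sum"`, the default -- molecule counts are additive)
#' or removed entirely (`"drop"`).
#'
#' @param a,b `expression_matrix` objects.
#' @param case_insensitive logical; match symbols after upper-casing.
#' @param duplicate_policy `"sum"` or `"drop"`.
#' @return An object of class `"paired_expression"`: list with `side_a`,
#'   `side_b` (both `expression_matrix` with identical row order) and
#'   `common_genes` (the matching keys, sorted, no duplicates).
#' @examples
#' a <- expression_matrix(matrix(1:6, 3), c("A", "B", "C"), c("x", "y"),
#'                        c("t1", "t2"))
#' b <- expression_matrix(matrix(1:6, 3), c("B", "C", "D"), c("p", "q"),
#'                        c("s1", "s2"))
#' intersect_genes(a, b)$common_genes
#' @export
intersect_genes <- function(a, b, case_insensitive = FALSE,
                            duplicate_policy = c("sum", "drop")) {
  stopifnot(inherits(a, "expression_matrix"), inherits(b, "expression_matrix"))
  duplicate_policy <- match.arg(duplicate_policy)
  key <- function(sym) if (case_insensitive) toupper(sym) else sym
  ka <- key(a$gene_symbols)
  kb <- key(b$gene_symbols)
  collapse <- function(m, k) {
    dup <- unique(k[duplicated(k)])
    if (length(dup) == 0) {
      v <- m$values
      rownames(v) <- k
      return(v)
    }
    if (duplicate_policy == "drop") {
      keep <- !(k %in% dup)
      v <- m$values[keep, , drop = FALSE]
      rownames(v) <- k[keep]
      return(v)
    }
    v <- rowsum(m$values, group = k, reorder = FALSE)
    v
  }
  va <- collapse(a, ka)
  vb <- collapse(b, kb)
  common <- intersect(rownames(va), rownames(vb))
  if (length(common) == 0)
    stop("no common gene symbols between the two matrices")
  common <- sort(common, method = "radix")
  pa <- expression_matrix(va[common, , drop = FALSE], common,
                          a$cell_ids, a$labels)
  pb <- expression_matrix(vb[common, , drop = FALSE], common,
                          b$cell_ids, b$labels)
  structure(list(side_a = pa, side_b = pb, common_genes = common),
            class = "paired_expression")
}

#' @export
print.paired_expression <- function(x, ...) {
  cat("paired_expression: N =", length(x$common_genes), "common genes;",
      "side A:", ncol(x$side_a$values), "cells;",
      "side B:", ncol(x$side_b$values), "cells\n")
  invisible(x)
}
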
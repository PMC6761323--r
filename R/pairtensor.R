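#' Build the gene-summed pair matrix
#'
#' The two datasets are notionally joined into a three-mode array
#' x_ijk = x_ij * x_ik (genes x cells_A x cells_B), which is far too large
#' to materialize or decompose at single-cell scale. Summing over the
#' shared gene mode collapses it to the M x K matrix
#' x_jk = sum_i x_ij * x_ik, i.e. the cross-product of the two expression
#' matrices. That collapse is exact for the downstream SVD and is all this
#' function computes; genes are streamed in row blocks so the full
#' three-mode array never exists.
#'
#' No centering, log-transform, or normalization is applied: the method
#' consumes the matrices as distributed. Use `pre_transform` in [tdfe()]
#' if a transform is wanted.
#'
#' @param paired a `paired_expression` from [intersect_genes()].
#' @param block_size number of gene rows processed per block.
#' @return Dense numeric matrix, cells_A x cells_B.
#' @export
build_pair_matrix <- function(paired, block_size = 4096L) {
  stopifnot(inherits(paired, "paired_expression"))
  a <- paired$side_a$values
  b <- paired$side_b$values
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("expression values must be finite")
  n <- nrow(a)
  out <- matrix(0, ncol(a), ncol(b))
  for (start in seq.int(1L, n, by = block_size)) {
    idx <- start:min(start + block_size - 1L, n)
    out <- out + crossprod(a[idx, , drop = FALSE], b[idx, , drop = FALSE])
  }
  dimnames(out) <- list(colnames(a), colnames(b))
  out
}

#' Singular value decomposition of the pair matrix
#'
#' Decomposes the cells_A x cells_B pair matrix as
#' x_jk = sum_l lambda_l u_lj v_lk, yielding paired cell singular vectors:
#' column l of `vectors_a` lives on the cells of side A, column l of
#' `vectors_b` on the cells of side B, and sharing the index l is what ties
#' the two datasets together. Only min(M, K) paired components exist;
#' components beyond that have zero singular value and are never produced.
#'
#' Each singular vector's sign is ambiguous; for reproducibility the
#' entry of u_l with the largest magnitude is made positive (flipping v_l
#' with it), so repeated runs on the same input are bitwise identical.
#'
#' @param pair_matrix numeric matrix from [build_pair_matrix()].
#' @param rank_limit keep only the top `rank_limit` components; `NULL`
#'   (default) keeps all min(M, K).
#' @return Object of class `"cell_svd"`: list with `singular_values`
#'   (length L, descending), `vectors_a` (M x L, orthonormal columns),
#'   `vectors_b` (K x L, orthonormal columns).
#' @export
decompose_pair <- function(pair_matrix, rank_limit = NULL) {
  pair_matrix <- as.matrix(pair_matrix)
  if (any(!is.finite(pair_matrix))) stop("pair matrix must be finite")
  full <- min(dim(pair_matrix))
  if (is.null(rank_limit)) rank_limit <- full
  rank_limit <- as.integer(rank_limit)
  if (rank_limit < 1 || rank_limit > full)
    stop("rank_limit must lie in 1..min(M, K) = ", full)
  s <- svd(pair_matrix, nu = rank_limit, nv = rank_limit)
  u <- s$u
  v <- s$v
  for (l in seq_len(rank_limit)) {
    piv <- which.max(abs(u[, l]))
    if (u[piv, l] < 0) {
      u[, l] <- -u[, l]
      v[, l] <- -v[, l]
    }
  }
  rownames(u) <- rownames(pair_matrix)
  rownames(v) <- colnames(pair_matrix)
  colnames(u) <- colnames(v) <- paste0("l", seq_len(rank_limit))
  structure(list(singular_values = s$d[seq_len(rank_limit)],
                 vectors_a = u, vectors_b = v),
            class = "cell_svd")
}

#' @export
print.cell_svd <- function(x, ...) {
  l <- length(x$singular_values)
  cat("cell_svd: ", l, " components; cells ", nrow(x$vectors_a), " (A) x ",
      nrow(x$vectors_b), " (B); top singular values: ",
      paste(signif(utils::head(x$singular_values, 3), 4), collapse = ", "),
      if (l > 3) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Project expression onto cell singular vectors to get gene loadings
#'
#' The gene singular vectors are the projections of each side's expression
#' matrix onto its cell singular vectors: u_li = sum_j u_lj x_ij and
#' v_li = sum_k v_lk x_ik. They inherit the pairing by l and satisfy the
#' bilinear identity sum_i u_li v_l'i = lambda_l when l = l' and 0
#' otherwise, which ties gene space back to the decomposition.
#'
#' @param paired the `paired_expression` the SVD was built from.
#' @param svd a `cell_svd` from [decompose_pair()].
#' @return Object of class `"gene_loadings"`: list with `loadings_a`,
#'   `loadings_b` (both N genes x L components).
#' @export
project_genes <- function(paired, svd) {
  stopifnot(inherits(paired, "paired_expression"), inherits(svd, "cell_svd"))
  a <- paired$side_a$values
  b <- paired$side_b$values
  if (ncol(a) != nrow(svd$vectors_a))
    stop("side A has ", ncol(a), " cells but vectors_a has ",
         nrow(svd$vectors_a), " rows")
  if (ncol(b) != nrow(svd$vectors_b))
    stop("side B has ", ncol(b), " cells but vectors_b has ",
         nrow(svd$vectors_b), " rows")
  la <- a %*% svd$vectors_a
  lb <- b %*% svd$vectors_b
  rownames(la) <- rownames(lb) <- paired$common_genes
  structure(list(loadings_a = la, loadings_b = lb), class = "gene_loadings")
}

#' Export a decomposition as delimited text
#'
#' Writes the singular values and, per component, the paired cell vectors
#' and gene loadings as plain TSV tables for downstream inspection.
#'
#' @param svd a `cell_svd`.
#' @param loadings optional `gene_loadings`.
#' @param dir output directory, created if absent.
#' @return The directory path, invisibly.
#' @export
export_decomposition <- function(svd, loadings = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(l = seq_along(svd$singular_values),
               lambda = svd$singular_values),
    file.path(dir, "singular_values.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  dump <- function(m, prefix, fname) {
    d <- as.data.frame(m)
    names(d) <- paste0(prefix, seq_len(ncol(m)))
    d <- cbind(id = rownames(m), d)
    utils::write.table(d, file.path(dir, fname), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  dump(svd$vectors_a, "u_", "cell_vectors_a.tsv")
  dump(svd$vectors_b, "v_", "cell_vectors_b.tsv")
  if (!is.null(loadings)) {
    dump(loadings$loadings_a, "u_", "gene_loadings_a.tsv")
    dump(loadings$loadings_b, "v_", "gene_loadings_b.tsv")
  }
  invisible(dir)
}
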
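#' Tensor-decomposition-based unsupervised feature extraction
#'
#' Fits the full integration model to a pair of expression matrices that
#' share their gene index: (1) collapse the notional genes x cells_A x
#' cells_B product array to the gene-summed pair matrix
#' x_jk = sum_i x_ij x_ik; (2) decompose it by SVD into paired cell
#' singular vectors; (3) select components whose cell vectors are
#' associated with the categorical cell labels on each side
#' (categorical-regression F-test, BH-adjusted P < `vector_threshold`);
#' (4) score every gene by the chi-squared sum of its squared standardized
#' loadings on the selected components and select genes with BH-adjusted
#' P < `gene_threshold`; (5) quantify the coincidence of the two sides'
#' selections with confusion tables, odds ratios, and Fisher exact tests.
#'
#' If no component passes the vector selection on one side, the fit is
#' returned with an empty gene selection for that side (and a message);
#' that is the expected outcome on label-independent data.
#'
#' @param paired a `paired_expression` from [intersect_genes()], or a
#'   `synthetic_pair` from [generate_pair()].
#' @param vector_threshold adjusted-P cutoff for component selection.
#' @param gene_threshold adjusted-P cutoff for gene selection.
#' @param rank_limit number of components to compute; default all
#'   min(M, K).
#' @param pre_transform `NULL` (default: consume values as distributed),
#'   `"log1p"`, or a function applied to each side's value matrix before
#'   the pair matrix is built.
#' @return Object of class `"tdfe"`: list with `paired`, `svd`
#'   (`cell_svd`), `loadings` (`gene_loadings`), `vectors`
#'   (`vector_selection`), `genes` (`gene_selection`, or `NULL` when a
#'   side selected no components), `coincidence` (report list), `dims`
#'   (N, M, K), `call`.
#' @examples
#' fit <- tdfe(generate_pair(synthetic_spec(n_genes = 60, n_cells_a = 40,
#'   n_cells_b = 40, n_levels_a = 2, n_levels_b = 2, planted_genes = 6,
#'   seed = 1)))
#' summary(fit)
#' @export
tdfe <- function(paired, vector_threshold = 0.01, gene_threshold = 0.01,
                 rank_limit = NULL, pre_transform = NULL) {
  cl <- match.call()
  truth <- NULL
  if (inherits(paired, "synthetic_pair")) {
    truth <- paired$truth
    paired <- paired$paired
  }
  stopifnot(inherits(paired, "paired_expression"))
  if (!is.null(pre_transform)) {
    f <- if (is.function(pre_transform)) pre_transform
         else switch(match.arg(pre_transform, "log1p"), log1p = log1p)
    paired$side_a$values <- f(paired$side_a$values)
    paired$side_b$values <- f(paired$side_b$values)
  }
  x <- build_pair_matrix(paired)
  s <- decompose_pair(x, rank_limit = rank_limit)
  loadings <- project_genes(paired, s)
  vectors <- select_vectors(s, paired = paired, threshold = vector_threshold)
  genes <- NULL
  if (length(vectors$omega_a) > 0 && length(vectors$omega_b) > 0) {
    genes <- select_genes(loadings, vectors, threshold = gene_threshold)
  } else {
    message("no components selected on side ",
            if (length(vectors$omega_a) == 0) "A" else "B",
            "; gene selection is empty")
  }
  fit <- structure(
    list(paired = paired, svd = s, loadings = loadings,
         vectors = vectors, genes = genes,
         coincidence = coincidence_report(vectors, genes),
         dims = c(N = length(paired$common_genes),
                  M = ncol(paired$side_a$values),
                  K = ncol(paired$side_b$values)),
         truth = truth, call = cl),
    class = "tdfe")
  fit
}

#' @export
print.tdfe <- function(x, ...) {
  cat("Tensor-decomposition-based unsupervised feature extraction\n")
  cat("  N =", x$dims["N"], "common genes; M =", x$dims["M"],
      "cells (A) x K =", x$dims["K"], "cells (B)\n")
  cat("  components selected:", length(x$vectors$omega_a), "(A),",
      length(x$vectors$omega_b), "(B) of", length(x$vectors$pvalues_a), "\n")
  if (!is.null(x$genes))
    cat("  genes selected:", sum(x$genes$selected_a), "(A),",
        sum(x$genes$selected_b), "(B),", sum(x$genes$selected_both),
        "(both)\n")
  else cat("  genes selected: none (no label-associated components)\n")
  invisible(x)
}

#' Summarize an integration fit
#'
#' @param object a `tdfe` fit.
#' @param ... unused.
#' @return Object of class `"summary.tdfe"`: selection counts, both
#'   coincidence tables, and (for synthetic inputs carrying a truth set)
#'   the recovery metrics.
#' @export
summary.tdfe <- function(object, ...) {
  l <- seq_along(object$vectors$pvalues_a)
  vt <- coincidence_table(l %in% object$vectors$omega_a,
                          l %in% object$vectors$omega_b,
                          universe = "components")
  gt <- if (!is.null(object$genes))
    coincidence_table(object$genes$selected_a, object$genes$selected_b,
                      universe = "genes")
  rec <- if (!is.null(object$truth) && !is.null(object$genes))
    recovery_metrics(object$genes, object$truth)
  structure(list(dims = object$dims,
                 n_components = length(l),
                 omega_a = object$vectors$omega_a,
                 omega_b = object$vectors$omega_b,
                 vector_table = vt, gene_table = gt,
                 genes = object$genes, recovery = rec),
            class = "summary.tdfe")
}

#' @export
print.summary.tdfe <- function(x, ...) {
  cat("N =", x$dims["N"], "genes; M =", x$dims["M"], "x K =",
      x$dims["K"], "cells;", x$n_components, "paired components\n\n")
  cat("Component selection (|Omega_A| = ", length(x$omega_a),
      ", |Omega_B| = ", length(x$omega_b), "):\n", sep = "")
  print(x$vector_table)
  if (!is.null(x$gene_table)) {
    cat("\nGene selection:\n")
    print(x$gene_table)
  }
  if (!is.null(x$recovery))
    cat("\nPlanted-gene recovery: precision ",
        round(x$recovery$precision, 3), ", recall ",
        round(x$recovery$recall, 3), ", F1 ", round(x$recovery$f1, 3),
        "\n", sep = "")
  invisible(x)
}

#' Gene scores of a fit
#'
#' @param object a `tdfe` fit.
#' @param ... unused.
#' @return N x 2 matrix of chi-squared gene scores (`score_a`, `score_b`),
#'   or `NULL` if no genes were scored.
#' @export
coef.tdfe <- function(object, ...) {
  if (is.null(object$genes)) return(NULL)
  m <- cbind(score_a = object$genes$scores_a,
             score_b = object$genes$scores_b)
  rownames(m) <- object$genes$genes
  m
}

#' Coincidence-by-rank plot
#'
#' Plots which components are selected on each side along the rank axis l
#' (components ordered by decreasing singular value): circles for side A,
#' triangles for side B, crosses joined by vertical lines where both
#' sides select the same l. Jointly selected components concentrating at
#' small l is the visual signature of a successful integration.
#'
#' @param x a `tdfe` fit.
#' @param max_l plot only components up to this rank (default all).
#' @param ... passed to `plot`.
#' @export
plot.tdfe <- function(x, max_l = NULL, ...) {
  cbr <- coincidence_by_rank(x$vectors)
  r <- cbr$records
  if (!is.null(max_l)) r <- r[r$l <= max_l, ]
  graphics::plot(NA, xlim = range(r$l), ylim = c(0.5, 3.5), yaxt = "n",
                 xlab = "component l", ylab = "", ...)
  graphics::axis(2, at = c(1, 2, 3), labels = c("B", "both", "A"), las = 1)
  both <- r$l[r$class == "both"]
  if (length(both))
    graphics::segments(both, 1, both, 3, lty = 2, col = "grey60")
  graphics::points(r$l[r$selected_a & r$class != "both"],
                   rep(3, sum(r$selected_a & r$class != "both")), pch = 1)
  graphics::points(both, rep(2, length(both)), pch = 4, col = "blue")
  graphics::points(r$l[r$selected_b & r$class != "both"],
                   rep(1, sum(r$selected_b & r$class != "both")),
                   pch = 2, col = "red")
  invisible(x)
}
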
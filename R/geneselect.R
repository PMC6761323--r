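#' Standardize one gene-loading column
#'
#' Centers a gene singular vector by its mean over genes and scales by its
#' sample standard deviation (N - 1 denominator). The chi-squared gene
#' score accumulates squares of these standardized loadings. A
#' zero-variance column cannot be standardized and is excluded from
#' scoring by the caller.
#'
#' @param x numeric vector of loadings for one component (length N genes).
#' @return Standardized values, or `NULL` (with a warning) when the sample
#'   standard deviation is zero.
#' @export
standardize_loadings <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 genes to standardize")
  s <- stats::sd(x)
  if (s == 0) {
    warning("zero-variance loading column excluded from gene scoring")
    return(NULL)
  }
  (x - mean(x)) / s
}

#' Chi-squared gene scores and P-values over selected components
#'
#' For each gene, sums the squared standardized loadings over the selected
#' component set Omega and converts the score to an upper-tail P-value of
#' the chi-squared distribution with df = |Omega|. Under the working
#' assumption that loadings are Gaussian across genes, unremarkable genes
#' get uniform P-values while genes loading strongly on the selected
#' components fall in the upper tail. Zero-variance columns are dropped
#' from Omega (with a warning) and the degrees of freedom reduced
#' accordingly.
#'
#' @param loadings N x L numeric matrix of gene loadings for one side.
#' @param omega integer vector of selected component indices.
#' @return List with `scores` (length N, >= 0), `pvalues`, `df` (effective
#'   |Omega|), `omega` (components actually used), and per-component
#'   `means` and `sds`.
#' @export
chi2_gene_pvalues <- function(loadings, omega) {
  loadings <- as.matrix(loadings)
  omega <- as.integer(omega)
  if (length(omega) == 0)
    stop("no components were selected (empty omega); ",
         "gene scoring requires at least one label-associated singular vector")
  if (any(omega < 1 | omega > ncol(loadings)))
    stop("omega indices out of range 1..", ncol(loadings))
  mu <- colMeans(loadings[, omega, drop = FALSE])
  sdev <- apply(loadings[, omega, drop = FALSE], 2, stats::sd)
  keep <- sdev > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance loading column(s) dropped from omega")
    omega <- omega[keep]
    mu <- mu[keep]
    sdev <- sdev[keep]
    if (length(omega) == 0)
      stop("all selected loading columns have zero variance")
  }
  z <- sweep(loadings[, omega, drop = FALSE], 2, mu, "-")
  z <- sweep(z, 2, sdev, "/")
  scores <- rowSums(z^2)
  df <- length(omega)
  list(scores = unname(scores),
       pvalues = stats::pchisq(scores, df = df, lower.tail = FALSE),
       df = df, omega = omega, means = unname(mu), sds = unname(sdev))
}

#' Select genes loading on the selected singular vectors
#'
#' Runs the chi-squared scoring on each side with that side's selected
#' component set, BH-adjusts the gene P-values within each side over all N
#' genes, and flags genes with adjusted P strictly below the threshold.
#'
#' @param loadings a `gene_loadings` from [project_genes()].
#' @param selection a `vector_selection` from [select_vectors()].
#' @param threshold adjusted-P cutoff, default 0.01 (strict `<`).
#' @return Object of class `"gene_selection"`: per-side scores, raw and
#'   adjusted P-values, selection flags, degrees of freedom, and the gene
#'   symbols; `selected_both` marks genes selected on both sides.
#' @export
select_genes <- function(loadings, selection, threshold = 0.01) {
  stopifnot(inherits(loadings, "gene_loadings"),
            inherits(selection, "vector_selection"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  side <- function(mat, omega) {
    r <- chi2_gene_pvalues(mat, omega)
    r$adjusted <- bh_adjust(r$pvalues)
    r$selected <- r$adjusted < threshold
    r
  }
  a <- side(loadings$loadings_a, selection$omega_a)
  b <- side(loadings$loadings_b, selection$omega_b)
  structure(list(genes = rownames(loadings$loadings_a),
                 scores_a = a$scores, pvalues_a = a$pvalues,
                 adjusted_a = a$adjusted, selected_a = a$selected,
                 df_a = a$df, means_a = a$means, sds_a = a$sds,
                 omega_a = a$omega,
                 scores_b = b$scores, pvalues_b = b$pvalues,
                 adjusted_b = b$adjusted, selected_b = b$selected,
                 df_b = b$df, means_b = b$means, sds_b = b$sds,
                 omega_b = b$omega,
                 selected_both = a$selected & b$selected,
                 threshold = threshold),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat("gene_selection: ", sum(x$selected_a), " genes on side A, ",
      sum(x$selected_b), " on side B, ", sum(x$selected_both),
      " on both (of ", length(x$genes), "; adjusted P < ", x$threshold,
      ")\n", sep = "")
  invisible(x)
}

#' Per-gene results table
#'
#' @param x a `gene_selection`.
#' @param ... unused.
#' @return A data.frame with columns `gene`, `score_a`, `p_a`, `p_adj_a`,
#'   `selected_a`, `score_b`, `p_b`, `p_adj_b`, `selected_b`,
#'   `selected_both`.
#' @export
as.data.frame.gene_selection <- function(x, ...) {
  data.frame(gene = x$genes,
             score_a = x$scores_a, p_a = x$pvalues_a,
             p_adj_a = x$adjusted_a, selected_a = x$selected_a,
             score_b = x$scores_b, p_b = x$pvalues_b,
             p_adj_b = x$adjusted_b, selected_b = x$selected_b,
             selected_both = x$selected_both)
}

#' Write ranked gene-symbol lists
#'
#' Writes three plain-text lists (one symbol per line): genes selected on
#' side A, on side B, and on both, each ordered by increasing raw P-value
#' on the relevant side (side A for the intersection). The lists are ready
#' for upload to external enrichment services.
#'
#' @param x a `gene_selection`.
#' @param dir output directory, created if absent.
#' @return Character vector of the three file paths, invisibly.
#' @export
write_gene_lists <- function(x, dir) {
  stopifnot(inherits(x, "gene_selection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(flags, order_p, fname) {
    g <- x$genes[flags][order(order_p[flags])]
    path <- file.path(dir, fname)
    writeLines(g, path)
    path
  }
  paths <- c(emit(x$selected_a, x$pvalues_a, "genes_side_a.txt"),
             emit(x$selected_b, x$pvalues_b, "genes_side_b.txt"),
             emit(x$selected_both, x$pvalues_a, "genes_both.txt"))
  invisible(paths)
}
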
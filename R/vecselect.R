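#' Categorical-regression P-value for one cell singular vector
#'
#' Regresses a cell singular vector on the unordered cell labels (time
#' point, cell type, ...) and returns the whole-model F-test P-value of
#' the categorical fit against the intercept-only model -- the model-level
#' P-value `lm` reports. Treating the labels as unordered categories means
#' any kind of label dependence counts, not only monotone trends. With G
#' non-empty levels and n cells the test has (G - 1, n - G) degrees of
#' freedom; it is invariant to the choice of reference level and to affine
#' transforms of the vector.
#'
#' A constant vector (zero variance, so neither explained nor residual
#' variance) carries no label information and is assigned P = 1.
#'
#' @param vector numeric values, one per cell.
#' @param labels factor (or coercible), one level per cell; empty levels
#'   are dropped before fitting.
#' @return A single P-value in \[0, 1\].
#' @export
categorical_pvalue <- function(vector, labels) {
  vector <- as.numeric(vector)
  f <- droplevels(factor(labels))
  if (length(vector) != length(f))
    stop("vector and labels differ in length")
  g <- nlevels(f)
  if (g < 2) stop("need at least 2 label levels, got ", g)
  n <- length(vector)
  if (n <= g) stop("need more cells (", n, ") than label levels (", g, ")")
  if (stats::var(vector) == 0) return(1)
  fit <- stats::lm(vector ~ f)
  fs <- summary(fit)$fstatistic
  if (is.null(fs) || !is.finite(fs[["value"]])) return(1)
  unname(stats::pf(fs[["value"]], fs[["numdf"]], fs[["dendf"]],
                   lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment: with P-values sorted
#' ascending, q_i = min over j >= i of p_j * n / j, clipped at 1 and
#' returned in the original order. Thin validating wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of raw P-values in \[0, 1\].
#' @return Adjusted P-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("P-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Select cell singular vectors associated with the cell labels
#'
#' Attributes a categorical-regression P-value to every cell singular
#' vector on each side, BH-adjusts within each side separately (the
#' selected sets are defined per side), and selects components with
#' adjusted P strictly below the threshold. The selected index sets
#' (`omega_a`, `omega_b`) drive the gene scoring.
#'
#' @param svd a `cell_svd` from [decompose_pair()].
#' @param labels_a,labels_b per-cell labels for sides A and B; defaults
#'   are taken from `paired` if supplied.
#' @param threshold adjusted-P cutoff, default 0.01 (strict `<`).
#' @param paired optionally, the `paired_expression`, as a convenience
#'   source for both label vectors.
#' @return Object of class `"vector_selection"`: lists `pvalues_a/b`,
#'   `adjusted_a/b`, `omega_a/b` (integer component indices), `threshold`,
#'   `lambda`.
#' @export
select_vectors <- function(svd, labels_a = NULL, labels_b = NULL,
                           threshold = 0.01, paired = NULL) {
  stopifnot(inherits(svd, "cell_svd"))
  if (!is.null(paired)) {
    if (is.null(labels_a)) labels_a <- paired$side_a$labels
    if (is.null(labels_b)) labels_b <- paired$side_b$labels
  }
  if (length(labels_a) != nrow(svd$vectors_a))
    stop("labels_a has length ", length(labels_a), ", expected ",
         nrow(svd$vectors_a))
  if (length(labels_b) != nrow(svd$vectors_b))
    stop("labels_b has length ", length(labels_b), ", expected ",
         nrow(svd$vectors_b))
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  p_a <- apply(svd$vectors_a, 2, categorical_pvalue, labels = labels_a)
  p_b <- apply(svd$vectors_b, 2, categorical_pvalue, labels = labels_b)
  adj_a <- bh_adjust(p_a)
  adj_b <- bh_adjust(p_b)
  structure(list(pvalues_a = unname(p_a), pvalues_b = unname(p_b),
                 adjusted_a = unname(adj_a), adjusted_b = unname(adj_b),
                 omega_a = which(adj_a < threshold),
                 omega_b = which(adj_b < threshold),
                 threshold = threshold,
                 lambda = svd$singular_values),
            class = "vector_selection")
}

#' @export
print.vector_selection <- function(x, ...) {
  cat("vector_selection: ", length(x$omega_a), " / ", length(x$pvalues_a),
      " components selected on side A, ", length(x$omega_b), " / ",
      length(x$pvalues_b), " on side B (adjusted P < ", x$threshold,
      ")\n", sep = "")
  invisible(x)
}

#' Per-component selection table
#'
#' One row per component l: singular value, raw and BH-adjusted P-values,
#' and selection flags for both sides -- the data behind a coincidence-
#' by-rank plot.
#'
#' @param x a `vector_selection`.
#' @param ... unused.
#' @return A data.frame with columns `l`, `lambda`, `p_a`, `p_adj_a`,
#'   `selected_a`, `p_b`, `p_adj_b`, `selected_b`.
#' @export
as.data.frame.vector_selection <- function(x, ...) {
  l <- seq_along(x$pvalues_a)
  data.frame(l = l, lambda = x$lambda,
             p_a = x$pvalues_a, p_adj_a = x$adjusted_a,
             selected_a = l %in% x$omega_a,
             p_b = x$pvalues_b, p_adj_b = x$adjusted_b,
             selected_b = l %in% x$omega_b)
}
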
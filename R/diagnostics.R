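#' Cross-tabulate two selections over a shared universe
#'
#' Counts the four joint categories of two selection flag vectors over the
#' same universe of items (singular-vector components, or common genes):
#' both selected (`n11`), A only (`n10`), B only (`n01`), neither
#' (`n00`). Association is summarized by the sample cross-product odds
#' ratio and a two-sided Fisher exact test; a strong excess of jointly
#' selected items is the coincidence evidence that the two datasets were
#' integrated meaningfully.
#'
#' @param selected_a,selected_b logical vectors of equal length (the
#'   universe), or integer index sets interpreted against `universe_size`.
#' @param universe_size required when index sets are given.
#' @param universe short description of what was counted (for printing).
#' @return Object of class `"coincidence_table"`: counts `n11`, `n10`,
#'   `n01`, `n00`, `universe_size`, `universe`, `sample_odds_ratio`
#'   (`Inf` when a denominator cell is 0 and the numerator is positive,
#'   `NaN` when both vanish), `cml_odds_ratio` (conditional maximum-
#'   likelihood estimate), `fisher_p` (two-sided exact P; 1 when a margin
#'   is zero, in which case the odds ratio is flagged `NA`).
#' @examples
#' coincidence_table(c(TRUE, TRUE, FALSE, FALSE, FALSE),
#'                   c(FALSE, TRUE, TRUE, FALSE, FALSE))
#' @export
coincidence_table <- function(selected_a, selected_b, universe_size = NULL,
                              universe = "items") {
  if (!is.logical(selected_a) || !is.logical(selected_b)) {
    if (is.null(universe_size))
      stop("universe_size is required when selections are index sets")
    to_flags <- function(idx) {
      idx <- as.integer(idx)
      if (length(idx) && (min(idx) < 1 || max(idx) > universe_size))
        stop("selection index outside universe 1..", universe_size)
      seq_len(universe_size) %in% idx
    }
    selected_a <- to_flags(selected_a)
    selected_b <- to_flags(selected_b)
  }
  if (length(selected_a) != length(selected_b))
    stop("selections cover different universes (", length(selected_a),
         " vs ", length(selected_b), " items)")
  n11 <- sum(selected_a & selected_b)
  n10 <- sum(selected_a & !selected_b)
  n01 <- sum(!selected_a & selected_b)
  n00 <- sum(!selected_a & !selected_b)
  fe <- fisher_exact(n11, n10, n01, n00)
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 universe_size = length(selected_a), universe = universe,
                 sample_odds_ratio = fe$sample_odds_ratio,
                 cml_odds_ratio = fe$cml_odds_ratio,
                 fisher_p = fe$p),
            class = "coincidence_table")
}

#' Fisher exact test and odds ratios for a 2x2 table
#'
#' Two-sided exact P-value (sum of hypergeometric probabilities no larger
#' than that of the observed table, as `stats::fisher.test` computes it)
#' together with two odds-ratio estimates: the sample cross-product ratio
#' (n11 * n00) / (n10 * n01) and the conditional maximum-likelihood
#' estimate from the exact test. The two can differ noticeably for
#' extreme tables, so both are reported, clearly labeled.
#'
#' @param n11,n10,n01,n00 nonnegative integer cell counts (both, A only,
#'   B only, neither).
#' @return List with `p`, `sample_odds_ratio`, `cml_odds_ratio`. When a
#'   row or column margin is zero the table carries no association
#'   information: `p` is 1 and both odds ratios are `NA`.
#' @export
fisher_exact <- function(n11, n10, n01, n00) {
  cells <- c(n11, n10, n01, n00)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  if ((n11 + n10 == 0) || (n01 + n00 == 0) ||
      (n11 + n01 == 0) || (n10 + n00 == 0))
    return(list(p = 1, sample_odds_ratio = NA_real_,
                cml_odds_ratio = NA_real_))
  tab <- matrix(c(n11, n01, n10, n00), 2)
  ft <- stats::fisher.test(tab)
  num <- as.numeric(n11) * as.numeric(n00)
  den <- as.numeric(n10) * as.numeric(n01)
  s_or <- if (den > 0) num / den else if (num > 0) Inf else NaN
  list(p = ft$p.value, sample_odds_ratio = s_or,
       cml_odds_ratio = unname(ft$estimate))
}

#' @export
print.coincidence_table <- function(x, ...) {
  cat("coincidence over ", x$universe_size, " ", x$universe, ":\n", sep = "")
  m <- matrix(c(x$n11, x$n01, x$n10, x$n00), 2,
              dimnames = list(`side B` = c("selected", "not selected"),
                              `side A` = c("selected", "not selected")))
  print(m)
  cat("sample odds ratio: ", format(x$sample_odds_ratio, digits = 6),
      "; conditional MLE: ", format(x$cml_odds_ratio, digits = 6),
      "; Fisher two-sided P: ", format(x$fisher_p, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Per-component coincidence records
#'
#' Classifies every component l as selected on both sides, one side only,
#' or neither, and summarizes where each class sits along the rank axis
#' (jointly selected components concentrate at small l, i.e. large
#' singular values, when the integration works).
#'
#' @param selection a `vector_selection`.
#' @return List with `records` (data.frame: `l`, `selected_a`,
#'   `selected_b`, `class`) and `median_l` (named numeric, median rank per
#'   class; `NA` for empty classes).
#' @export
coincidence_by_rank <- function(selection) {
  stopifnot(inherits(selection, "vector_selection"))
  l <- seq_along(selection$pvalues_a)
  sa <- l %in% selection$omega_a
  sb <- l %in% selection$omega_b
  cls <- ifelse(sa & sb, "both",
         ifelse(sa, "a_only", ifelse(sb, "b_only", "neither")))
  cls <- factor(cls, levels = c("both", "a_only", "b_only", "neither"))
  med <- vapply(levels(cls), function(k) {
    if (any(cls == k)) stats::median(l[cls == k]) else NA_real_
  }, 0)
  list(records = data.frame(l = l, selected_a = sa, selected_b = sb,
                            class = cls),
       median_l = med)
}

#' Assemble the full coincidence report
#'
#' One structured summary of an integration run: the vector and gene
#' confusion tables with odds ratios and Fisher P-values, the selection
#' counts, and problem dimensions. `format = "json"` gives a string ready
#' to write to disk.
#'
#' @param vectors a `vector_selection`.
#' @param genes a `gene_selection`, or `NULL` when no components were
#'   selected on a side.
#' @param format `"list"` or `"json"`.
#' @return Nested list, or a JSON string.
#' @export
coincidence_report <- function(vectors, genes = NULL, format = c("list", "json")) {
  format <- match.arg(format)
  l <- seq_along(vectors$pvalues_a)
  vt <- coincidence_table(l %in% vectors$omega_a, l %in% vectors$omega_b,
                          universe = "components")
  tab_as_list <- function(t) {
    list(n11 = t$n11, n10 = t$n10, n01 = t$n01, n00 = t$n00,
         universe_size = t$universe_size, universe = t$universe,
         sample_odds_ratio = t$sample_odds_ratio,
         cml_odds_ratio = t$cml_odds_ratio, fisher_p = t$fisher_p)
  }
  rep <- list(
    vectors = list(selected_a = length(vectors$omega_a),
                   selected_b = length(vectors$omega_b),
                   threshold = vectors$threshold,
                   coincidence = tab_as_list(vt)))
  if (!is.null(genes)) {
    gt <- coincidence_table(genes$selected_a, genes$selected_b,
                            universe = "genes")
    rep$genes <- list(selected_a = sum(genes$selected_a),
                      selected_b = sum(genes$selected_b),
                      selected_both = sum(genes$selected_both),
                      threshold = genes$threshold,
                      coincidence = tab_as_list(gt))
  }
  if (format == "json")
    return(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null"))
  rep
}
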
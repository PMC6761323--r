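#' Reported coincidence tables from the two motivating study designs
#'
#' The published confusion matrices for the two integration designs the
#' method was developed on: human vs mouse embryonic midbrain development
#' (time-point labels) and mouse hypothalamus with vs without acute
#' formalin stress (cell-type labels), one table each for the
#' singular-vector selection and the gene selection. Shipped as package
#' data so the coincidence statistics (odds ratios, Fisher P-values) can
#' be recomputed from the printed cell counts without any download.
#'
#' Side A is human (midbrain) or the without-stress condition
#' (hypothalamus); side B is mouse or with-stress. For the midbrain
#' tables the printed cells are reproduced exactly as published even
#' where their sums disagree slightly with the stated universe sizes.
#'
#' @param study optionally restrict to one `study` id.
#' @return A data.frame with columns `study`, `items`, `n11` (both
#'   selected), `n10` (A only), `n01` (B only), `n00` (neither),
#'   `universe_size`.
#' @examples
#' tabs <- reported_coincidence_tables()
#' with(tabs[tabs$study == "midbrain_genes", ],
#'      fisher_exact(n11, n10, n01, n00)$sample_odds_ratio)
#' @export
reported_coincidence_tables <- function(study = NULL) {
  path <- system.file("extdata", "reported_coincidence_tables.tsv",
                      package = "tdufe", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(study)) {
    d <- d[d$study %in% study, , drop = FALSE]
    if (nrow(d) == 0) stop("unknown study id: ", paste(study, collapse = ", "))
  }
  d
}
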
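# Small programmatic fixtures shared across test files.

# Expression matrix with Poisson-ish counts and round-robin labels.
rand_expr <- function(n_genes, n_cells, n_levels = 2, seed = 1,
                      prefix = "c") {
  set.seed(seed)
  vals <- matrix(rpois(n_genes * n_cells, lambda = 4), n_genes)
  expression_matrix(vals,
                    sprintf("G%03d", seq_len(n_genes)),
                    paste0(prefix, seq_len(n_cells)),
                    rep(paste0("t", seq_len(n_levels)),
                        length.out = n_cells))
}

# Paired object over a shared (already sorted) gene set.
rand_pair <- function(n_genes, n_cells_a, n_cells_b, n_levels = 2,
                      seed = 1) {
  a <- rand_expr(n_genes, n_cells_a, n_levels, seed = seed, prefix = "a")
  b <- rand_expr(n_genes, n_cells_b, n_levels, seed = seed + 1000,
                 prefix = "b")
  intersect_genes(a, b)
}

# Independent step-up BH oracle, written from the definition
# q_i = min_{j >= i} p_(j) * n / j (ranks j over ascending p), clipped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (pos in seq_len(n)) {
    i <- ord[pos]
    cand <- Inf
    for (pos2 in pos:n) {
      j <- ord[pos2]
      cand <- min(cand, p[j] * n / pos2)
    }
    q[i] <- min(1, cand)
  }
  q
}

# Two-sided Fisher oracle: sum of hypergeometric probabilities not
# exceeding that of the observed table (same relative-tolerance rule
# R's exact test documents).
fisher_oracle <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  r1 <- n11 + n10
  c1 <- n11 + n01
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  obs <- probs[n11 - lo + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# 4-line dense TSV fixture: 1 metadata row (labels doubling as ids),
# 2 genes x 3 cells.
write_tiny_dense <- function(path, bad_cell = FALSE, negative = FALSE) {
  lines <- c("gene\tday1\tday1\tday2",
             "Gapdh\t1\t2\t3",
             "Actb\t4\t5\t6")
  if (bad_cell) lines[2] <- "Gapdh\t1\tNA\t3"
  if (negative) lines[3] <- "Actb\t4\t-5\t6"
  writeLines(lines, path)
  path
}
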
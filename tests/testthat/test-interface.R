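small_fit <- function() {
  pair <- generate_pair(synthetic_spec(n_genes = 200, n_cells_a = 80,
                                       n_cells_b = 80, n_levels_a = 2,
                                       n_levels_b = 2, planted_genes = 15,
                                       effect_size = 5, seed = 3))
  tdfe(pair)
}

test_that("the fitted object exposes the modelling interface", {
  fit <- small_fit()
  expect_s3_class(fit, "tdfe")
  expect_equal(unname(fit$dims), c(200, 80, 80))
  expect_output(print(fit), "genes selected")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.tdfe")
  expect_output(print(sm), "Planted-gene recovery")
  cf <- coef(fit)
  expect_equal(dim(cf), c(200L, 2L))
  expect_true(all(cf >= 0))
  pdf(NULL)
  expect_invisible(plot(fit, max_l = 40))
  dev.off()
})

test_that("pre-transform hook is off by default and changes the fit", {
  pair <- generate_pair(synthetic_spec(n_genes = 100, n_cells_a = 40,
                                       n_cells_b = 40, n_levels_a = 2,
                                       n_levels_b = 2, planted_genes = 8,
                                       effect_size = 5, seed = 12))
  fit_raw <- suppressMessages(tdfe(pair))
  fit_log <- suppressMessages(tdfe(pair, pre_transform = "log1p"))
  expect_false(isTRUE(all.equal(fit_raw$svd$singular_values,
                                fit_log$svd$singular_values)))
  # raw fit consumed values exactly as distributed
  expect_identical(fit_raw$paired$side_a$values, pair$paired$side_a$values)
})

test_that("simulate driver writes files and a valid manifest, reproducibly", {
  spec <- synthetic_spec(n_genes = 60, n_cells_a = 20, n_cells_b = 20,
                         n_levels_a = 2, n_levels_b = 2, planted_genes = 6,
                         seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_simulate(spec, d1)
  r2 <- run_simulate(spec, d2)
  expect_true(all(file.exists(r1$paths)))
  expect_identical(readLines(r1$paths["side_a"]),
                   readLines(r2$paths["side_a"]))
  manifest <- jsonlite::read_json(r1$paths[["truth"]],
                                  simplifyVector = TRUE)
  expect_equal(manifest$planted_indices, r1$pair$truth)
  expect_equal(manifest$spec$effect_size, 4)
})

test_that("integration driver runs end-to-end and is deterministic", {
  spec <- synthetic_spec(n_genes = 150, n_cells_a = 60, n_cells_b = 60,
                         n_levels_a = 3, n_levels_b = 3, planted_genes = 12,
                         effect_size = 5, seed = 31)
  simdir <- withr::local_tempdir()
  sim <- run_simulate(spec, simdir)
  make_cfg <- function(out) list(
    side_a = list(path = sim$paths[["side_a"]]),
    side_b = list(path = sim$paths[["side_b"]]),
    out_dir = out)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  fit <- suppressMessages(run_integration(read_run_config(make_cfg(out1))))
  suppressMessages(run_integration(read_run_config(make_cfg(out2))))
  artifacts <- c("components.tsv", "genes.tsv", "genes_side_a.txt",
                 "genes_side_b.txt", "genes_both.txt", "coincidence.json",
                 "run_log.txt")
  expect_true(all(file.exists(file.path(out1, artifacts))))
  for (f in setdiff(artifacts, "run_log.txt"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  report <- jsonlite::read_json(file.path(out1, "coincidence.json"),
                                simplifyVector = TRUE)
  expect_equal(report$genes$selected_both, sum(fit$genes$selected_both))
  # written component table matches the fit
  comp <- read.delim(file.path(out1, "components.tsv"))
  expect_equal(which(comp$selected_a), as.integer(fit$vectors$omega_a))
  # gene lists agree with the selection flags
  expect_setequal(readLines(file.path(out1, "genes_both.txt")),
                  fit$genes$genes[fit$genes$selected_both])
})

test_that("run configuration validates thresholds and fills defaults", {
  cfg <- read_run_config(list(side_a = list(path = "a"),
                              side_b = list(path = "b")))
  expect_equal(cfg$vector_threshold, 0.01)
  expect_equal(cfg$duplicate_policy, "sum")
  expect_error(read_run_config(list(vector_threshold = 1.5)),
               "vector_threshold")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("gene_threshold: 0.05",
               "side_a:", "  path: x.tsv",
               "side_b:", "  path: y.tsv"), path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$gene_threshold, 0.05)
  expect_equal(cfg2$side_a$path, "x.tsv")
})

test_that("reported coincidence tables load and are internally consistent", {
  tabs <- reported_coincidence_tables()
  expect_equal(nrow(tabs), 4)
  expect_true(all(c("n11", "n10", "n01", "n00") %in% names(tabs)))
  h <- reported_coincidence_tables("hypothalamus_genes")
  expect_equal(h$n11 + h$n10 + h$n01 + h$n00, h$universe_size)
  expect_error(reported_coincidence_tables("nope"), "unknown study")
})
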
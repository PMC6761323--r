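test_that("dense reader parses a CEF-style dump with a label row", {
  path <- write_tiny_dense(withr::local_tempfile(fileext = ".tsv"))
  m <- read_dense(path, dense_dialect(meta_rows = 1, label_row = 1))
  expect_s3_class(m, "expression_matrix")
  expect_equal(dim(m$values), c(2L, 3L))
  expect_equal(m$gene_symbols, c("Gapdh", "Actb"))
  expect_equal(as.character(m$labels), c("day1", "day1", "day2"))
  expect_equal(unname(m$values), matrix(1:6, 2, byrow = TRUE))
})

test_that("dense reader rejects malformed files with located errors", {
  bad <- write_tiny_dense(withr::local_tempfile(fileext = ".tsv"),
                          bad_cell = TRUE)
  expect_error(read_dense(bad, dense_dialect()),
               "non-numeric data cell at line 2, column 3")
  neg <- write_tiny_dense(withr::local_tempfile(fileext = ".tsv"),
                          negative = TRUE)
  expect_error(read_dense(neg, dense_dialect()),
               "negative expression value at line 3, column 3")
  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tc1\tc2", "Gapdh\t1\t2", "Actb\t3"), ragged)
  expect_error(read_dense(ragged, dense_dialect()), "ragged row: line 3")
  nolab <- write_tiny_dense(withr::local_tempfile(fileext = ".tsv"))
  expect_error(read_dense(nolab, dense_dialect(label_row = NA)),
               "no label row")
})

test_that("dense writer round-trips values and metadata exactly", {
  m <- rand_expr(7, 5, n_levels = 3, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dense(m, path)
  m2 <- read_dense(path, dense_dialect(meta_rows = 2, label_row = 2))
  expect_identical(m2$values, m$values)
  expect_identical(m2$gene_symbols, m$gene_symbols)
  expect_identical(m2$cell_ids, m$cell_ids)
  expect_identical(m2$labels, m$labels)
})

test_that("sparse triplet reader densifies and matches the dense path", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 3", "1 1 5", "2 1 1", "2 2 7"),
             file.path(dir, "m.mtx"))
  writeLines(c("G1", "G2"), file.path(dir, "genes.txt"))
  writeLines(c("c1", "c2"), file.path(dir, "cells.txt"))
  writeLines(c("t1", "t2"), file.path(dir, "labels.txt"))
  m <- read_sparse_triplets(file.path(dir, "m.mtx"),
                            file.path(dir, "genes.txt"),
                            file.path(dir, "cells.txt"),
                            file.path(dir, "labels.txt"))
  expect_equal(unname(m$values), matrix(c(5, 1, 0, 7), 2))

  # random fixture: dense and sparse routes agree bitwise
  d <- rand_expr(9, 6, n_levels = 2, seed = 3)
  d$values[d$values < 3] <- 0
  mm <- Matrix::Matrix(d$values, sparse = TRUE)
  Matrix::writeMM(mm, file.path(dir, "r.mtx"))
  writeLines(d$gene_symbols, file.path(dir, "rg.txt"))
  writeLines(d$cell_ids, file.path(dir, "rc.txt"))
  writeLines(as.character(d$labels), file.path(dir, "rl.txt"))
  m2 <- read_sparse_triplets(file.path(dir, "r.mtx"),
                             file.path(dir, "rg.txt"),
                             file.path(dir, "rc.txt"),
                             file.path(dir, "rl.txt"))
  expect_identical(unname(m2$values), unname(d$values))
  expect_identical(m2$labels, d$labels)
})

test_that("sparse reader validates dimensions and indices", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "3 1 5"), file.path(dir, "bad.mtx"))
  writeLines(c("G1", "G2"), file.path(dir, "genes.txt"))
  writeLines(c("c1", "c2"), file.path(dir, "cells.txt"))
  writeLines(c("t1", "t2"), file.path(dir, "labels.txt"))
  expect_error(read_sparse_triplets(file.path(dir, "bad.mtx"),
                                    file.path(dir, "genes.txt"),
                                    file.path(dir, "cells.txt"),
                                    file.path(dir, "labels.txt")))
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "1 1 5"), file.path(dir, "ok.mtx"))
  writeLines(c("G1", "G2", "G3"), file.path(dir, "genes3.txt"))
  expect_error(read_sparse_triplets(file.path(dir, "ok.mtx"),
                                    file.path(dir, "genes3.txt"),
                                    file.path(dir, "cells.txt"),
                                    file.path(dir, "labels.txt")),
               "3 gene symbols")
})

test_that("expression_matrix enforces its invariants", {
  v <- matrix(1:6, 2)
  expect_error(expression_matrix(v, "A", paste0("c", 1:3), c("x", "x", "y")),
               "gene symbols")
  expect_error(expression_matrix(v, c("A", "B"), "c1", c("x", "x", "y")),
               "cell ids")
  expect_error(expression_matrix(matrix(c(1, -1, 0, 2, 3, 4), 2),
                                 c("A", "B"), paste0("c", 1:3),
                                 c("x", "x", "y")),
               "nonnegative")
  expect_error(expression_matrix(v, c("A", "B"), paste0("c", 1:3),
                                 c("x", "x", "x")),
               "2 distinct")
  m <- expression_matrix(v, c("A", "B"), paste0("c", 1:3),
                         c("x", NA, ""))
  expect_equal(as.character(m$labels), c("x", "unknown", "unknown"))
})

test_that("gene intersection matches, collapses duplicates, and sorts", {
  a <- expression_matrix(matrix(1:6, 3), c("A", "B", "C"), c("x", "y"),
                         c("t1", "t2"))
  b <- expression_matrix(matrix(1:6, 3), c("B", "C", "D"), c("p", "q"),
                         c("s1", "s2"))
  p <- intersect_genes(a, b)
  expect_equal(p$common_genes, c("B", "C"))
  expect_equal(unname(p$side_a$values), matrix(c(2, 3, 5, 6), 2))

  # set symmetry
  q <- intersect_genes(b, a)
  expect_setequal(p$common_genes, q$common_genes)

  # case rule
  mouse <- expression_matrix(matrix(1:2, 1), "Gapdh", c("x", "y"),
                             c("t1", "t2"))
  human <- expression_matrix(matrix(3:4, 1), "GAPDH", c("p", "q"),
                             c("s1", "s2"))
  expect_error(intersect_genes(mouse, human), "no common gene symbols")
  pc <- intersect_genes(mouse, human, case_insensitive = TRUE)
  expect_equal(pc$common_genes, "GAPDH")

  # duplicates: sum adds the rows, drop removes the symbol entirely
  dup <- expression_matrix(matrix(c(1, 10, 2, 20, 3, 30), 3,
                                  byrow = FALSE),
                           c("A", "A", "B"), c("x", "y"),
                           c("t1", "t2"))
  other <- expression_matrix(matrix(1:4, 2), c("A", "B"), c("p", "q"),
                             c("s1", "s2"))
  psum <- intersect_genes(dup, other, duplicate_policy = "sum")
  expect_equal(unname(psum$side_a$values["A", ]), c(1 + 10, 20 + 3))
  pdrop <- intersect_genes(dup, other, duplicate_policy = "drop")
  expect_equal(pdrop$common_genes, "B")
})
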
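Package: tdufe
Title: Tensor-Decomposition-Based Unsupervised Feature Extraction for
    Paired Expression Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates two gene-expression matrices that share a gene
    index (two species, or two treatment conditions) by singular value
    decomposition of the gene-summed cells-by-cells cross-product matrix.
    Cell singular vectors associated with categorical cell metadata are
    selected by categorical-regression F-tests with Benjamini-Hochberg
    correction, genes loading on the selected vectors are scored by a
    chi-squared statistic, and coincidence of the two selections is
    quantified with 2x2 confusion tables, odds ratios, and Fisher exact
    tests. Includes readers for dense delimited and Matrix Market
    expression dumps, a synthetic paired-count generator with planted
    label-dependent genes for end-to-end validation, and a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
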
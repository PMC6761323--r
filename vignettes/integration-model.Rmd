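---
title: "Integrating paired expression matrices by cross-product SVD"
author: "tdufe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating paired expression matrices by cross-product SVD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdufe)
```

## The problem

Single-cell expression experiments produce thousands of cells but only a
handful of per-cell annotations — a time point, a coarse cell type, a
treatment arm. When two such datasets measure the same biological
process (two species over development, one tissue with and without a
stressor), the analysis question is which genes respond to that
annotation *coherently in both datasets*. Genes selected independently
per dataset and intersected afterwards agree poorly; this package
instead couples the datasets *before* any selection happens.

## Model and procedure

Let $x_{ij} \in \mathbb{R}^{N \times M}$ and
$x_{ik} \in \mathbb{R}^{N \times K}$ be the two genes $\times$ cells
matrices over the same $N$ gene symbols (after
`intersect_genes()`). Conceptually the datasets are joined into the
three-mode array $x_{ijk} = x_{ij} x_{ik}$, which shares its gene mode;
at single-cell scale ($N \sim 10^4$, $M, K \sim 10^3$) that array has
$\sim 10^{10}$ entries and cannot be decomposed directly. Summing over
the shared gene mode collapses it exactly to the pair matrix

$$x_{jk} = \sum_{i=1}^{N} x_{ij}\, x_{ik},$$

an $M \times K$ cross-product for which the tensor decomposition reduces
to an ordinary SVD,

$$x_{jk} = \sum_{\ell=1}^{\min(M,K)} \lambda_\ell\, u_{\ell j}\, v_{\ell k}.$$

The cell singular vectors $u_\ell$ and $v_\ell$ are paired by $\ell$:
each pair captures one mode of covariation that the two datasets
express jointly. Only $\min(M, K)$ paired components exist; the package
never considers null-space completions beyond that rank.

**Component selection.** Each cell vector is regressed on the unordered
cell labels, $u_{\ell j} = a_\ell + \sum_t a_{\ell t} \delta_{jt}$ (and
analogously for $v_{\ell k}$), and assessed by the whole-model F-test
against the intercept-only model — the model-level P-value an `lm` fit
reports, with $(G-1, n-G)$ degrees of freedom for $G$ non-empty levels.
We deliberately interpret the categorical regression through its
model-level test rather than per-coefficient tests: the dummy expansion
with an intercept is over-parameterized, and only the whole-model F is
invariant to the choice of reference level. Treating labels as
unordered means any label dependence counts, not only monotone trends.
P-values are BH-adjusted within each side separately (the selected sets
$\Omega^A, \Omega^B$ are defined per side) and components pass at
adjusted $P < 0.01$, strict inequality. Cells with a missing label form
a genuine `"unknown"` level rather than being dropped.

**Gene selection.** Gene singular vectors are the projections
$u_{\ell i} = \sum_j u_{\ell j} x_{ij}$,
$v_{\ell i} = \sum_k v_{\ell k} x_{ik}$. For each side, the selected
columns are standardized over genes (mean over the $N$ genes; sample
standard deviation with the $N-1$ denominator — at $N \sim 10^4$ the
population/sample distinction is numerically immaterial, but one
convention must be fixed for reproducibility, and the sample form is
the default of the statistical environment this implementation lives
in). The gene score is $\sum_{\ell \in \Omega} z_{\ell i}^2$, referred
to $\chi^2_{|\Omega|}$; the Gaussian working assumption behind that
reference is *not* claimed to be calibrated on real loadings — on real
data the P-values are a ranking device, which is why the coincidence
diagnostics below matter. Gene P-values are BH-adjusted within side
over all $N$ genes and selected at adjusted $P < 0.01$. Zero-variance
loading columns cannot be standardized; they are dropped from $\Omega$
with the degrees of freedom reduced, rather than producing infinities.

**Coincidence diagnostics.** The two sides' selections are
cross-tabulated over their shared universe (components up to
$\min(M,K)$, or the $N$ common genes) and association is summarized by
the sample cross-product odds ratio $(n_{11} n_{00})/(n_{10} n_{01})$
and a two-sided Fisher exact test. The conditional-MLE odds ratio from
the exact test is reported alongside the sample ratio, clearly
labeled, because the two estimators can differ noticeably for extreme
tables and published tables rarely say which was printed.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `vector_threshold` | 0.01 | BH-adjusted P cutoff for components (strict `<`) |
| `gene_threshold` | 0.01 | BH-adjusted P cutoff for genes (strict `<`) |
| `rank_limit` | `min(M, K)` | components computed |
| `pre_transform` | `NULL` | optional `log1p` or custom transform |
| `case_insensitive` | `FALSE` | upper-case symbols before pairing |
| `duplicate_policy` | `"sum"` | collapse duplicate symbols by summation |

No normalization, centering, or log-transform is applied by default:
the method is defined on expression values as distributed (molecule
counts), and the whole pipeline is invariant to a global rescaling of
either matrix, which removes the most common motivation for
normalizing. The `pre_transform` hook exists for users who want a
variance-stabilized fit, but it changes the model being fitted and is
off by default. Duplicate gene symbols are summed because molecule
counts are additive and summation is deterministic; `"drop"` removes
ambiguous symbols entirely for users who prefer caution over signal.

## Numerical choices

* The SVD backend is deterministic; because each singular vector is
  defined only up to a joint sign flip of $(u_\ell, v_\ell)$, a
  canonical rule (the largest-magnitude entry of $u_\ell$ is made
  positive, ties broken by first index) makes repeated runs bitwise
  identical. All downstream statistics are invariant to these flips.
* The pair matrix is accumulated in gene blocks (`block_size = 4096`),
  so neither input is duplicated at full size; the result is exact
  regardless of block size.
* A constant cell vector has neither explained nor residual variance;
  its categorical P is defined as 1 (it carries no label information).
* Degenerate 2×2 tables: a zero margin yields Fisher $P = 1$ and an
  undefined (NA) odds ratio; a zero off-diagonal product with nonzero
  diagonal yields an infinite sample odds ratio, reported as `Inf`.
* If no component passes selection on one side, gene selection is
  empty by definition; `tdfe()` reports that outcome rather than
  erroring, since it is the expected result on label-independent data.
* Indices in all interfaces are 1-based, the R convention.

## The synthetic generator

`synthetic_spec()` / `generate_pair()` emulate the data structure the
model assumes: two nonnegative count matrices over a shared gene set,
each cell carrying one categorical label, with a planted subset of
genes whose mean depends on the label *in both datasets*. Each planted
gene gets a random on/off program over side A's label levels (at least
one level on and one off); side B reuses the program through a cyclic
level mapping — shared program membership, not shared values, mirroring
the premise that paired components capture shared biology. Counts are
negative binomial (variance $\mu + \phi\mu^2$), the standard model for
molecule counts; a lognormal option exists for continuity checks.

Defaults — 1,000 genes, 300 cells per side over 5 levels, 50 planted
genes, 4-fold on-level shift, baseline mean 5, dispersion $\phi = 0.1$,
seed 7 — define the reference recovery experiment: a clearly detectable
but not trivial signal (a 4-fold change in a dispersed count model) at
roughly the planted-gene fraction (5%) a real developmental program
might occupy, and small enough that the full pipeline runs in about a
second. All randomness flows from the single spec seed through a
private RNG stream, so generation is bitwise reproducible and does not
disturb the caller's RNG.

What the generator does **not** emulate: library-size variation,
dropout, batch effects, correlated gene programs beyond the planted
one. Passing the recovery tests therefore shows the pipeline's
machinery is correct and calibrated under its own assumptions, not that
the χ² null is well calibrated on real single-cell data.

## Validation strategy and problem sizes

The test suite checks every stage against an independent oracle: the
pair matrix against a literal triple-loop collapse of the three-mode
array; the decomposition against Frobenius reconstruction,
orthonormality, and the bilinear identity
$\sum_i u_{\ell i} v_{\ell' i} = \lambda_\ell \delta_{\ell\ell'}$; the
categorical P against the pooled t-test (two groups) and a
20,000-draw permutation null (four groups); BH against an explicit
step-up loop; the χ² tail against numerical integration; Fisher's
exact P against full hypergeometric enumeration for every 2×2 table
with total at most 60 (evaluated once per symmetry orbit, which the
two-sided P is invariant under). Calibration is checked under
simulated global nulls (2,000 regression P-values; 10,000 gene
P-values at $|\Omega| = 3$), and end-to-end behavior on the reference
synthetic experiment (recovery F1) and its label-independent
counterpart over 20 seeds (selection rate). These sizes keep the whole
suite around two minutes while leaving each check statistically
meaningful.

## Known limitations

* The χ² gene null assumes Gaussian loadings; on real data treat gene
  P-values as a ranking, and judge the run by the coincidence odds
  ratios.
* Time points and cell types are unordered categories by design; a
  genuinely ordinal analysis (trend tests) is out of scope.
* Enrichment of the selected genes against external services is out of
  scope; `write_gene_lists()` exports upload-ready symbol lists.
* The spreadsheet sources some repositories distribute must be
  converted to delimited text or Matrix Market first; only text
  formats are parsed.
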
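---
title: "Methods: models, estimators and design choices in phenodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in phenodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodiv)
```

# The trial model

`phenodiv` analyses balanced completely randomized designs: `g` genotypes
(in the motivating application, spatially delimited subpopulations of a
*restinga* cactus treated as genotypes), each scored on `k` replicates for
a panel of quantitative traits. The working model per trait is the
additive two-component decomposition

$$y_{ij} = \mu + g_i + e_{ij}, \qquad
  g_i \sim (0, \sigma^2_g), \quad e_{ij} \sim (0, \sigma^2_e),$$

so that on the mean-square scale $E[QM_g] = k\sigma^2_g + \sigma^2_e$ and
$E[QM_r] = \sigma^2_e$. Everything downstream — genetic parameters,
Scott–Knott tests, the Mahalanobis metric — is built from `QMg`, `QMr` and
the genotype means. Residual normality and homoscedasticity are assumed,
not re-tested here: users should run their preferred preflight checks
(`shapiro.test`, `bartlett.test`, ...) before trusting the F tests.

# Genetic-parameter estimators

From `genetic_parameters()`: $\hat\sigma^2_f = QM_g/k$,
$\hat\sigma^2_e = QM_r/k$, $\hat\sigma^2_g = (QM_g - QM_r)/k$ truncated at
zero, $h^2 = \hat\sigma^2_g/\hat\sigma^2_f$ (a broad-sense
*repeatability* of genotype means — no narrow-sense claim is made),
$CV_g = 100\,\hat\sigma_g/\bar y$ and $CV_e = 100\sqrt{QM_r}/\bar y$.

Two conventions deserve a note:

* **CVe uses the residual SD of single observations**, $\sqrt{QM_r}$, not
  the SD of means $\sqrt{QM_r/k}$. This is the convention under which the
  reference trial's published `CVg/CVe` column is reproduced exactly (for
  example plant height gives 0.67 and mean germination time 2.52), and it
  makes `CVe` identical to the experimental CV, which is therefore
  reported in both columns.
* **Negative genetic variance is truncated to zero** before `h²`, `CVg`
  and the ratio are formed (a trait whose genotype mean square falls below
  the residual mean square carries no usable signal), but the raw value is
  kept in `Vg_raw` for diagnostics.

Unbalanced data are rejected with an explicit error rather than
approximated: harmonic-mean corrections would silently change the meaning
of every estimator above.

# Scott–Knott mean grouping

`scott_knott()` recursively partitions the descending-sorted means. At a
node holding `g` means it finds the contiguous split maximizing the
between-group sum of squares $B_0$ (ties broken toward the smallest left
group, for determinism), forms

$$\hat\sigma^2_0 = \frac{\sum_i (\bar y_i - \bar y)^2 + \nu_r\, s^2_{\bar y}}
  {g + \nu_r}, \qquad s^2_{\bar y} = QM_r/k,$$

and splits when $\lambda = \frac{\pi}{2(\pi-2)} B_0/\hat\sigma^2_0$
exceeds the $\chi^2$ quantile at the chosen level with
$\nu = g/(\pi - 2)$ degrees of freedom. The fractional `ν` is used
directly in `qchisq()` — rounding it flips borderline decisions. Final
groups are contiguous runs of the sorted means; letters are assigned in
descending-mean order (`a` = highest), the agronomy convention.

# Divergence matrices

`mahalanobis_d2()` computes $D^2(i,i') = d^\top W^{-1} d$ on genotype mean
differences. $W$ defaults to the pooled residual covariance **divided by
k** — the covariance of genotype means — so the univariate $D^2$ sits on
the same scale as the ANOVA F statistic; the raw residual covariance is
available via `scale_to_means = FALSE`. The pooled covariance itself
(`pooled_residual_covariance()`) sums within-genotype centered
cross-products over genotypes and divides by the residual df $g(k-1)$; its
diagonal reproduces each trait's `QMr`, which the tests use as a
consistency check. Genotype x replicate rows missing any trait are dropped
(with a message) — a complete-case rule chosen over imputation because the
covariance feeds a matrix inverse.

When the covariance is near-singular (condition number above `1e10`) a
pseudo-inverse is substituted with a warning; results then depend on the
trait panel's rank and should be read with care.

`standardized_euclidean()` standardizes each trait column to mean 0,
variance 1 (sample variance, n − 1) and applies the Euclidean distance;
the "mean" variant divides the squared distance by the number of traits.
Both the D² path and the standardized-Euclidean path are supported for the
clustering stages, since both are used in practice for the same analyses;
the package does not privilege one.

# Clustering

**Tocher.** The inclusion limit θ is the largest nearest-neighbour
distance over all genotypes. The first group is seeded with the globally
closest pair; the unassigned genotype with the smallest mean distance to
the group joins while that mean is ≤ θ; otherwise the group closes and the
next is seeded from the closest remaining pair. This is the classic
plant-breeding formulation; an alternative rule that caps the *increase*
in group mean distance is exposed behind `criterion = "increase"` but is
not the default. All ties break lexicographically by genotype label.

**UPGMA and Mojena.** `upgma()` wraps average-linkage `stats::hclust()`
(size-weighted distance updates; fusion heights are non-decreasing).
`mojena_cut()` prunes the dendrogram at `mean(h) + c * sd(h)` over all
n − 1 fusion heights (sample SD; no trimming). The constant defaults to
`c = 1.25`, the value the method's follow-up literature recommends for
moderate numbers of objects; it is a parameter, not a fitted quantity.
Group count is monotone non-increasing in `c`.

# Trait importance

`singh_contribution()` decomposes each pair's $D^2$ into per-trait
components $d_j (W^{-1}d)_j$ and sums over pairs, so the trait totals
conserve the total pairwise $D^2$ exactly. With correlated traits a
component can be negative; it is reported signed, with a warning naming
the trait — flooring at zero is left to presentation layers so the
conservation identity remains testable.

`canonical_variates()` solves $W^{-1}B\,a = \lambda a$ with $W$ the pooled
within-genotype SSCP and $B = k \sum_i (\bar y_i - \bar y)(\bar y_i - \bar
y)^\top$, via the Cholesky factor of $W$ (a symmetric eigenproblem, more
stable than a direct non-symmetric solve). Coefficients are normalized to
$a^\top W a = 1$, which makes scores of distinct variates uncorrelated in
the within metric, and signs follow the convention that each variate's
largest-magnitude coefficient is positive. An exactly collinear trait
panel is refused (reciprocal condition number below `1e-12`).

# Genotype–ideotype selection

The ideotype defaults to the *observed* per-trait optimum (column maximum
for higher-is-better traits, minimum for lower-is-better ones, on the
standardized scale), matching common usage of the index in breeding
software; explicit raw-scale targets override it for ex-ante ideotypes.
Distances are weighted Euclidean on standardized means (default weights
1), ranked ascending with label tie-breaks. The default selected fraction
is 30% of genotypes. In the default trait panel only mean germination
time is lower-is-better; users studying, e.g., dwarfing would override the
directions.

# The synthetic generator

`simulate_trait_table()` draws genotype and residual effects from normal
distributions — the two-component model above says nothing about the
effect distributions, and normality is the standard neutral choice — with
a single RNG stream seeded explicitly per call. `simulate_germination()`
draws, per genotype, a germination probability on the logit scale (so it
stays in (0,1)) and a mean germination day; each seed germinates
independently with that probability, on a day drawn from a normal, rounded
half-up, clamped below at day 1; a drawn day beyond the counting window is
recorded as censored rather than clamped, avoiding an artificial pile-up
on the last day. The default configuration mirrors the reference trial:
20 genotypes, 4 replicates, 15 traits whose `σ²_g` and `σ²_e` are
back-solved from the published mean squares and whose grand means come
from the published CVs; germination uses 50 seeds per replicate counted
over 21 days. The generator deliberately omits genotype x environment
interaction, spatial structure, seed dormancy and within-replicate plant
heterogeneity (replicate means are modelled directly, since the trial
protocol pools plants within replicates). Passing tests on these data
therefore validate the estimators and algorithms under the stated model —
they do not certify behavior under G×E or non-normal residuals.

# Problem sizes and numerical tolerances

The test suite exercises: ANOVA against a brute-force sum-of-squares
oracle on 100 random 20 × 4 tables (relative tolerance 1e-10);
Scott–Knott against exhaustive split enumeration for up to 6 means, with
threshold-crossing checks solved in closed form; Mahalanobis identity
reduction (1e-12) and invariance under random nonsingular trait recodings
(1e-8) on 50 instances; Singh conservation to 1e-8 relative on 50
instances; Tocher partition checks on 100 random matrices plus an exact
planted two-cluster recovery at a 1:100 within:between ratio;
repeatability recovery over 500 simulated 20 × 4 trials (mean estimated
h² within ±0.05 of a true 0.80) and truncation behavior under a
no-signal trait; and a full pipeline run on the default 20 × 4 × 15
panel. These sizes give stable Monte-Carlo estimates while keeping the
suite quick to run.

# Known limitations

* Balanced designs only; unbalanced data are rejected, not modelled
  (REML/mixed models are out of scope).
* Single-environment trials; `h²` is a repeatability, inflated relative
  to narrow-sense heritability by any non-additive or G×E variance.
* D² requires an invertible (or pseudo-invertible) residual covariance:
  trait panels wider than the residual degrees of freedom will not work.
* The Scott–Knott chi-square approximation is asymptotic; with very few
  genotypes its nominal level is approximate.
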
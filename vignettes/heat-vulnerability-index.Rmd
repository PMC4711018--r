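---
title: "Building county-level heat vulnerability indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building county-level heat vulnerability indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatvuln)
```

## The problem and the model

Spatial heat vulnerability assessments rank areal units — here, counties
— by the demographic and socioeconomic susceptibility of their residents
to extreme heat, so that adaptation resources can be targeted before
health-outcome data exist. The additive-index tradition this package
implements works from a small set of pre-selected indicators and lets a
factor model find the latent structure, rather than weighting indicators
by hand.

The package is calibrated to a 73-county, high-altitude study region in
western China whose urban (city district/town) and rural (village)
populations are analyzed as separate strata. Ten indicators, all
percentages coded so that higher = more vulnerable, cover advanced age,
disability, illiteracy, social isolation, poverty (receipt of minimum
living allowances) and cramped dwellings; `hv_schema()` documents the
full set and fixes its order.

The construction, per stratum:

1. **Correlation.** Spearman rank correlations (tie-aware, mid-rank
   convention) describe the indicator relationships for reporting. The
   PCA itself runs by default on the Pearson correlation matrix of the
   raw indicators — the conventional "PCA of standardized variables" —
   with the input matrix an explicit, logged parameter, because runs
   driven by the packaged reference matrices necessarily use Spearman
   values (that is all that was published).
2. **Extraction and retention.** `pca_from_correlation()`
   eigendecomposes the correlation matrix; `retain_factors()` applies
   the Kaiser rule, keeping components with eigenvalue strictly greater
   than 1.
3. **Rotation.** `varimax_rotate()` maximizes the varimax criterion
   $V = \sum_j \left[ \sum_i \ell_{ij}^4/p - \left(\sum_i
   \ell_{ij}^2/p\right)^2 \right]$ by cyclic pairwise planar rotations,
   with Kaiser row-normalization on by default (the norm in this
   literature; it is a flag because some analyses omit it).
4. **Scoring.** `factor_scores()` computes regression (Thurstone)
   scores, $F = Z R^{-1} L$, re-standardized to mean 0, sample SD 1 per
   factor.
5. **Binning and summation.** `bin_score()` maps each standardized
   score to an integer category 1–6 by SD distance from the mean, and
   `build_index()` sums the four categories into the cumulative index
   (range 4–24 for four factors).

## Conventions the results depend on

Several steps of this construction are underdetermined in the
literature; the package fixes each one explicitly and logs its use in
the run manifest.

**Category boundaries.** The six categories are defined by SD cut
points at −2, −1, 0, 1, 2. The outer categories are closed ("2 or more
SD below/above"); for the inner boundaries we assign negative
boundaries outward (−1 falls in category 2), and zero and positive
boundaries upward (0 in category 4, 1 in category 5). This is symmetric
at ±2 and places the mean in category 4. Inputs landing exactly on a
boundary are counted and reported (`boundary_hits`), since any other
convention would move exactly those counties.

**Sign orientation.** An orthogonal rotation determines loading columns
only up to sign. After rotation each factor column is flipped so its
largest-magnitude loading is positive. Because all ten indicators are
coded so that higher means more vulnerable, this makes every factor
score point in the direction of greater vulnerability — required for an
additive index to be meaningful. Flips are recorded per factor.

**Factor ordering.** Retained factors are reordered by descending
post-rotation variance, reproducing the "factor 1 … factor 4"
presentation logic of published loading tables.

**Strict retention, with an explicit override.** `retain_factors()`
counts eigenvalues strictly greater than 1. `factor_solution()` and the
pipeline accept `n_factors` to fix the retained count instead, for
analyses where the component count is established externally (see the
next section for why the reference rural matrix needs this). The
manifest records which rule produced `k`.

**Scoring method.** Regression scoring is the default in the lineage of
vulnerability indices this package follows; other estimators (Bartlett,
Anderson–Rubin) are out of scope. The scoring matrix inverse is guarded
by a condition-number cap (default 1e8) so near-collinear indicator
sets fail loudly rather than amplify noise.

## The packaged reference matrices

The only quantitative data published by the source study are
per-stratum means/SDs/ranges, the two 10 × 10 Spearman matrices, and the
rotated loadings; the county microdata underneath was never deposited.
The two Spearman matrices are shipped as delimited-text fixtures,
transcribed cell by cell with a manifest (`fixture_manifest()`) that
records every printed value, its significance star, and three
transcription decisions: one urban cell printed with three decimals
(0.403, kept as printed), one rural cell printed without a leading zero
(−.30), and one rural cell (loss of labor ability × age 60+, printed
0.04 with a p ≤ 0.01 star that is impossible at that magnitude for
n = 73) kept as printed and flagged as a suspected misprint.

Two consequences of working from a two-decimal rendition deserve
emphasis:

* The matrices need not be exactly positive semi-definite. Rounding 45
  off-diagonal entries by up to 0.005 can shift eigenvalues by up to
  0.045 in operator norm; `pca_from_correlation()` therefore accepts
  eigenvalues down to −1e-6, clipping them to zero for variance shares
  with a warning.
* The same perturbation affects retention at the margin. On the urban
  matrix the Kaiser rule retains four components (eigenvalues 3.067,
  2.153, 1.345, 1.202). On the rural matrix the fourth eigenvalue comes
  out at 0.987 — 0.013 below the threshold, well inside the rounding
  band — so the strict rule retains three, although the source analysis,
  which ran on the raw microdata, identified four components in both
  strata. Reference-matrix runs therefore fix `n_factors = 4` (the
  `fixtures` pipeline mode does this by default), and the retained
  four-component variance shares come out at 77.67 % (urban) and
  76.58 % (rural), against 77.7 % and 76.5 % published. The
  acceptance suite asserts the strict-rule behaviour as specified and
  documents this discrepancy rather than papering over it.

Factor scores, indices and county summaries cannot be reproduced from
the reference matrices — they need the microdata — so fixture-mode runs
deliberately stop after the loading/variance stage and say so in the
manifest, rather than fabricate per-county output.

## The synthetic county generator

`generate_counties()` stands in for the unavailable microdata. It draws
a four-factor linear model: latent scores $F \sim N(0, I_4)$, loadings
$L$ from block presets encoding the published structure (a poverty
block, an elderly/fragile-health block, an isolation pair, a
small-dwelling pair; illiteracy joins the elderly block in the urban
preset and the dwelling block in the rural preset, the one structural
difference between strata), residuals with configurable uniqueness SD
(default 0.3), rescaling to unit variance, and mapping onto percentage
scales via the published per-stratum means and SDs. The true latent
scores and loadings are returned so recovery experiments can score the
pipeline against ground truth; `congruence()` computes the matched mean
Tucker coefficient over all column permutations and signs.

Design choices, made once:

* Latent factors are orthogonal in expectation only; their sample
  correlations are whatever the draw produces, as in a real census, so
  the scoring step genuinely exercises the inverse correlation matrix.
* Percent clipping is off by default: clipping distorts correlations,
  so recovery experiments run unclipped (values can then stray outside
  \[0, 100\], and the generator says so), while runs feeding the
  validated I/O layer set `clip_to_percent = TRUE`.
* Default `n_counties = 73` mirrors the study scale; recovery
  benchmarks use n = 200 over 20 seeds to separate method error from
  small-sample noise — at the study's own n the sampling noise of a
  73-row correlation matrix dominates.

What the generator does **not** emulate: the strong right skew of the
real marginals (several indicators have SD larger than their mean; a
normal linear model cannot match that support), spatial autocorrelation
between neighboring counties, and the administrative data-collection
process. Passing recovery tests therefore show the pipeline recovers a
known linear factor structure at realistic size and noise — they do not
show the real census data satisfies that model.

## Numerical choices

* Varimax converges when a full sweep improves the criterion by less
  than `tol` (default 1e-6), capped at `max_iter = 1000` sweeps;
  non-convergence is a flag and warning, not an error. The per-sweep
  criterion path is stored and is non-decreasing by construction
  (pairwise updates each maximize their pair's contribution); the test
  suite asserts this, checks k = 2 solutions against an exhaustive
  rotation-angle grid at 1e-5 resolution, and cross-checks k = 3
  solutions against an independent implementation.
* Eigen-decomposition ties are broken deterministically by fixing each
  eigenvector's sign (largest-magnitude component positive) before
  scaling by the square-rooted eigenvalue.
* Score columns are re-standardized exactly after the regression step,
  so the mean-0/SD-1 contract holds to 1e-10 regardless of conditioning.
* Round-trips: indicator tables and correlation matrices are written at
  fixed six-decimal precision, so write-then-read reproduces them
  bit-for-bit as decimal text; pipeline outputs carry no timestamps and
  re-running a manifest reproduces the bundle byte for byte.

## Limitations

The index is relative within a stratum and study region: scores are
standardized against the 73 counties analyzed, so values are not
comparable across regions or years without re-standardization. The
construction is unweighted (every factor contributes equally to the
sum), unvalidated against health outcomes, and restricted to the ten
indicators available at county level — exposure measures (land surface
temperature, air conditioning prevalence, occupation) are absent by
data availability, not by judgment. The choropleth step of the original
workflow is replaced by a GeoJSON property join (`export_geojson()`);
no boundary data is bundled.
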
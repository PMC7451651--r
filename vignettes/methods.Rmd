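---
title: "Valuing reclaimed mining-subsidence wetlands: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing reclaimed mining-subsidence wetlands: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecospill)
```

## The problem

In high-groundwater coal basins such as the North China Plain, mining
subsidence floods into permanent ponds and lakes. When such a subsided lake
is reclaimed into an artificial wetland park, two questions matter for
planning: how much did the area's *ecological regime* change, and how much
value did the restoration *spill over* onto surrounding land. `ecospill`
implements both assessments over ordinary, reproducible inputs: categorical
land-cover grids, point samples of appraised land prices, and planned-plot
polygons.

## Ecosystem-service valuation

The valuation is the Costanza-type benefit transfer

$$\mathrm{ESV} = \sum_i A_i \times VC_i,$$

with $A_i$ the area (hm²) of landscape class $i$ and $VC_i$ its value
coefficient (yuan·hm⁻²·a⁻¹). The built-in coefficient scheme
(`builtin_coefficients()`) covers seven classes; the two water classes carry
an eight-service breakdown in which the subsided (ponded) water body performs
no soil-formation and no recreation function and degraded shares of the rest.
Construction classes (urban, industry/transportation) carry *negative*
coefficients: their expansion is counted as ecological damage. Reports are in
万元 (wanyuan, 10⁴ yuan), because at study-area scale (≈5000 hm²) per-class
values are only readable in that unit; `yuan_to_wanyuan()` and friends make
the conversions explicit.

Areas come purely from cell counts (`tabulate_areas()`): a 10-m cell is
0.01 hm², so any area printed to two decimals in hm² is an exact integer
cell count and the accounting carries no polygonization error. Percentages
are rounded half-up to two decimals, the convention of the published tables.

Two reporting conventions deserve a note:

* **Change rates** are $(\mathrm{after}-\mathrm{before})/\mathrm{before}
  \times 100$ with the *signed* denominator. For a class with negative ESV
  this means a move toward zero prints negative — a shrinking of ecological
  damage — which is how the published tables print the built-up row
  (−193.46 → −169.98 as −12.14%).
* **Ecological storage** is the density index
  $\mathrm{ESS} = \frac{1}{h}\sum ESV_i / \sum A_i$ (万元·hm⁻²·a⁻¹, $h=1$
  for a single year's state). The conversion percent between two states is
  the *linear* annualization $(\mathrm{ESS}_{a}-\mathrm{ESS}_{b})/\text{years}
  \times 100$; a geometric rate would be ≈6.9% rather than 6.15% on the
  study values, and only the linear definition reproduces the published
  conversion table.

One inconsistency in the source tables is handled explicitly: the 2017
transportation and built-up ESVs printed in the valuation table imply
slightly different areas than the landscape-structure table prints
(238.85 vs 223.85 hm²; 965.52 vs 980.54 hm²). The package's fixtures follow
the area table; headline 2017 totals and change rates are validated against
the valuation table's own printed inputs (`panan_esv_printed()`), and
per-class recomputation is validated on the consistent cells.

## Geostatistics of land prices

Prices exist only at sample points; the spillover calculation needs
surfaces. The package implements the full chain itself rather than wrapping
a geostatistics library, since the chain *is* the method under study.

**Screening.** `normality_test()` (Shapiro–Wilk, pass at p ≥ 0.05, with a
log-transform recommendation on failure — never auto-applied) and
`morans_i()` (inverse-distance weights, row-standardized, one-sided
permutation p with 999 permutations by default). Both are advisory in the
pipeline: kriging does not strictly require normality, but a sample that
fails both screens has little business being interpolated.

**Variography.** `empirical_semivariogram()` uses the classical
Matheron estimator, $\hat\gamma(h_k) = \frac{1}{2N_k}\sum (z_i-z_j)^2$,
with 12 equal-width bins to half the maximum pairwise distance by default
(the field's conventional defaults; the source workflow names its software
but not its settings, so these are package choices, overridable).
`fit_variogram()` minimizes pair-count-weighted squared error by bounded
L-BFGS-B from a multi-start grid (nugget ≥ 0, partial sill ≥ 0, range ≤ 2×
max lag), per family (spherical, exponential, gaussian, pure nugget). The
range parameter convention is the plain one: true range for spherical, the
$e$-folding length for exponential/gaussian.

**Model selection.** `loo_cross_validate()` ranks candidates by
leave-one-out kriging RMSE, computed through the bordered-matrix identity
$e_i = (A^{-1}z^*)_i / (A^{-1})_{ii}$, which is algebraically identical to
refitting without point $i$ (the test suite asserts the identity against an
explicit refit). Ties break toward fewer parameters, then spherical <
exponential < gaussian. One caveat stated plainly: cross-validation ranks
*predictive* quality, and fitted spherical and exponential models are often
near-indistinguishable over the sampled lags, so the selected *family*
should not be over-interpreted — the selected model's surface is what
matters downstream, and that is what the recovery experiments validate.

**Kriging.** `ordinary_kriging()` solves the OK system with Lagrange
multiplier per 15-m cell. The default neighborhood is *global* (all
samples): at the sample sizes this design targets (n ≤ ~400) the exact
estimator is affordable as a single batched factorization, and a
neighborhood search is an approximation, not an improvement. A finite
`max_neighbors` switches to per-cell local systems for larger problems.
With the convention γ(0) = 0, kriging is an exact interpolator at sample
sites even with a nonzero nugget, the weight sums are 1 to machine
precision (asserted on every surface via the `max_weight_sum_err`
attribute), and the kriging variance at a sample site is zero.

Duplicate coordinates are averaged on ingest (`price_points()`) — they make
the system singular — with a message. No log-back-transform machinery is
included: the pipeline krigs raw prices, as the source workflow reports
raw-scale surfaces; users wanting log-space can transform on the way in.

## The spillover model

The three-step procedure:

1. **Average rise** (`average_rise()`):
   $r = (\overline{Lp^\alpha} - \overline{Lp^\beta}) / \overline{Lp^\beta}$
   over the region's surface cells. Averaging surface cells (not sample
   points) is chosen because the subtraction in step 2 is raster-based;
   the two averages would differ when sampling is uneven.
2. **Excess surface** (`excess_surface()`): cellwise
   $Lp^\alpha - Lp^\beta(1+r)$ — what remains after removing the
   market-wide rise. Cells with positive excess form the impact mask;
   negative cells stay in the grid but never count toward value.
3. **Spillover value** (`compute_sev()`):
   $\mathrm{SEV} = \sum_{ij} (Lp^\alpha_{ij} - Lp^\beta_{ij} -
   Lp^\beta_{ij} r_i) \times S_{ij}$ over planned plots, integrated as
   cell-sum × cell-area with cell-centre-in-polygon membership — the
   raster-calculator convention, bit-reproducible for a given grid.

Clipping to the positive mask (rather than letting negative excess offset
positive) follows the published procedure's definition of the impact range
as the area with values above zero; it also means SEV ≥ 0 by construction,
so the null experiment below matters. A single $r$ is used when only one
land-use type is sampled, but the data model carries the type label so
type-specific $r_i$ are supported.

## What the synthetic generator emulates

The study's actual inputs (classified satellite scenes; a proprietary
land-price survey) are not redistributable, so validation runs on synthetic
inputs with known truth:

* `generate_landcover()` grows spatially clustered class regions from
  seeded multi-source frontiers and stops each class exactly at its cell
  quota — tabulated areas equal the targets with zero error, which is what
  makes the published-table reproduction an exact test rather than a
  statistical one. Layouts are plausible patches, not replicas of real
  geography.
* `generate_price_field()` builds epoch 1 as planar baseline + stationary
  Gaussian random field (circulant-embedding synthesis, exact up to
  clipping of tiny negative embedding eigenvalues), epoch 2 as
  epoch 1 × (1+g) + a conical kernel $A\max(0, 1-d/R)$, and samples points
  uniformly with nugget-consistent noise. The kernel's zonal integral over
  the plots (`scenario_sev_true()`) is the ground truth the pipeline must
  recover; for a plot covering the disc it approaches the closed form
  $\pi A R^2/3$.

Default scenario (chosen once, by a priori signal-to-noise reasoning):
domain 3990 m × 3990 m (266×266 cells at 15 m), baseline plane
1200 + 0.04x + 0.02y yuan/m² (≈1200–1440), residual spherical variogram
(nugget 25, partial sill 900, range 900 m — appraised prices are smooth;
the small nugget reflects valuation noise, sd 5 yuan/m²), growth
g = 1.7681 (the magnitude of the study region's nine-year rise), kernel
A = 350 yuan/m² and R = 500 m at the domain centre, plots two half-disc
polygons of radius 1.1R, 300 samples per epoch. The reasoning: the plot
set must be small relative to the domain (otherwise the kernel itself
inflates $r$ and biases SEV low by roughly the plots/domain area ratio,
here ≈4%), while sampling must stay dense enough (≈230 m spacing against
R = 500 m) that positive-clipping of kriging noise in the plot margin does
not dominate. These biases partially cancel; the recovery experiment
(20 seeds) checks a median within 10% of truth, and a kernel-free null
checks that clipped noise stays below 2% of total plot value.

What the generator does **not** emulate: clustered sampling designs,
anisotropy, non-stationary variograms, land-use mixes with different
growth rates, classification error in the land-cover grids. Passing the
recovery tests therefore shows the estimator chain is correct and
well-behaved under stationary isotropic conditions, not that every survey
design would achieve the same accuracy.

## Numerical choices and degenerate inputs

* Variogram fitting: multi-start (8 starts × range grid) guards against
  local minima; a flat empirical variogram is won by the pure-nugget model.
* Kriging right-hand sides are built densely; the global solve is one
  LAPACK factorization with all cells as right-hand sides.
* LOO skips points whose reduced system is singular (warning); more than
  10% skipped is an error.
* All-nodata grids, constant prices, coincident points, mismatched grid
  geometries and non-representable area targets raise immediate errors
  naming the offender.
* Every stochastic routine takes an explicit seed; identical seeds give
  byte-identical outputs (asserted for rasters in the tests).

Problem sizes in the shipped tests and experiments — 266×266 analysis
grids, 300 points/epoch, 20 seeds per experiment — are the package's
validation design; they keep a full validation run in the minutes range
on a single core while leaving every estimate comfortably inside its
tolerance.

## Known limitations

* Ordinary kriging only: no universal/co-kriging, no anisotropy, no
  Bayesian uncertainty on variogram parameters. The excess surface
  inherits both epochs' kriging errors; with sparse samples the
  positive-clipping convention biases SEV upward (quantified by the null
  experiment).
* The average-rise correction removes *all* region-wide drivers jointly;
  if other localized projects moved prices during the study window their
  effect would be attributed to the wetland.
* Whether a trend surface should be removed before kriging is left to the
  user (none is removed by default, matching the source workflow's
  raw-scale surfaces).
* The valuation is benefit transfer: coefficients are regional constants,
  not site measurements, and no inflation adjustment is applied across
  epochs.
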
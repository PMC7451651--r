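# ecospill

Ecosystem-service valuation and land-price spillover analysis for
mining-subsidence areas reclaimed into wetland parks.

In high-groundwater coal basins, mining subsidence floods into permanent
"subsided lakes". Reclaiming such a lake into an artificial wetland changes
the area's ecological regime and raises the value of surrounding land.
`ecospill` quantifies both effects for planners and researchers working
with the ordinary artifacts of such a study: categorical land-cover grids
before/after reclamation, point samples of appraised land prices for two
epochs, and planned-plot polygons.

## What it computes

**Ecological regime.** From per-class areas `A_i` (hm²) and value
coefficients `VC_i` (yuan·hm⁻²·a⁻¹):

- ecosystem-service value `ESV = Σ A_i × VC_i`, per class and total, with
  contribution ratios and before/after change rates;
- ecological storage state `ESS = (1/h) · ΣESV_i / ΣA_i` (万元·hm⁻²) and
  its conversion quantity/percent between two states.

**Spillover.** From two epochs of price points `Lp` and planned plots
`S_ij`, the three-step procedure: ordinary kriging of both epochs onto a
shared 15-m grid (screening by Shapiro–Wilk and Moran's I; variogram
fitting with leave-one-out cross-validated model selection), removal of the
average regional rise `r = (mean_after − mean_before)/mean_before`,
and zonal integration of the positive excess
`SEV = Σ (Lp^α_ij − Lp^β_ij − Lp^β_ij · r_i) × S_ij` over the plots.

The geostatistics (empirical semivariogram, spherical/exponential/gaussian
model fitting, ordinary kriging with Lagrange multiplier, LOO
cross-validation, Moran permutation test) is implemented in the package and
validated against brute-force oracles in the test suite.

A synthetic-data module generates land-cover grids that hit any 2-decimal
hm² area targets *exactly* and two-epoch price fields (Gaussian random
field + growth + conical spillover kernel) with known ground-truth SEV, so
the whole pipeline is testable without the study's proprietary survey data.

## Worked example

```r
library(ecospill)

# valuation: build the study-area fixture and run the accounting
paths <- make_panan_fixture("fixture", seed = 1)
pipe <- esv_pipeline(paths$raster_2008, paths$raster_2017, paths$legend)
print(pipe$esv_before)
#>            class esv_wanyuan contribution_pct
#> 1     cultivated  1784.74583        49.769015
#> 2       woodland    65.00091         1.812600
#> 3      grassland    82.48369         2.300121
#> 4 transportation  -112.64756        -3.141264
#> 5  natural_water  1369.12695        38.179162
#> 6       built_up  -193.46311        -5.394868
#> 7 subsided_water   590.81148        16.475234
print(pipe$ess_before)
#> ecological storage state: 0.6754 wanyuan/hm2 (6754 yuan/hm2), h = 1 a
```

The 2008 valuation totals 3586.06 万元: cultivated land carries about half
the service value, the subsided water body 16.5%, and the negative rows are
the ecological cost of construction land. Dividing by the 5309.42 hm² study
area gives the storage state, 6754 yuan/hm².

```r
# spillover: synthetic scenario with known ground truth
sc <- scenario_spec()                       # 300 points/epoch, 15 m grid
gen <- generate_price_field(sc, seed = 1)
res <- run_spillover_pipeline(gen$points_before, gen$points_after,
                              sc$grid, gen$plots, seed = 1)
print(res)
#> spillover result: SEV = 83881691 yuan (0.84 yiyuan)
#>   average rise r = 1.7721 (177.21%)
#>   impact over plots: max 313.84, mean 92.74 yuan/m2; affected 94.42 hm2
gen$sev_true
#> [1] 91629818
```

The pipeline krigs both epochs, removes the 177% average rise, and
integrates the positive excess over the planned plots: here it recovers
91.5% of the scenario's true spillover value (the known conical kernel's
zonal integral).

The numbered drivers under `analysis/` run the same steps as a narrative
workflow (`01_landcover_fixture.R` … `04_spillover.R`), writing tables
under `results/`.

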
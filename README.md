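# rseicorridor

Ecological-quality analysis for linear corridors (canals, rivers, transport
corridors) from multiband remote-sensing rasters, built around the Remote
Sensing Ecological Index (RSEI) and an interpretable machine-learning
attribution of its spatial variation. A synthetic-landscape generator with
planted statistical structure makes the whole pipeline testable without any
satellite downloads.

## What it computes

**RSEI.** Four per-pixel component indices are derived from seven
reflectance bands and a land-surface-temperature layer:

- greenness `NDVI = (B2 - B1) / (B2 + B1)` (B1 red, B2 NIR),
- wetness `WET`, the tasseled-cap combination
  `0.1147 B1 + 0.2489 B2 + 0.2408 B3 + 0.3132 B4 - 0.3122 B5 - 0.6416 B6 - 0.5087 B7`,
- heat `LST = DN x 0.02 - 273.15` (deg C),
- dryness `NDBSI = (SI + IBI) / 2` from the bare-soil and built-up indices.

Each index is min-max normalized inside the analysis buffer, the four are
combined by covariance-matrix PCA per year, PC1 is sign-oriented so NDVI
and WET load positively, and the scores are rescaled:

```
RSEI = (PC1 - PC1_min) / (PC1_max - PC1_min)
```

with five equal-interval quality classes (poor, fair, moderate, good,
excellent).

**Corridor structure.** A 5-km bilateral buffer around the centerline,
subdivided into 500-m distance belts, with a north/south section split;
belt statistics, section summaries (Welch test on annual means) and class
area fractions.

**Distributions and trends.** Gaussian kernel density estimation
(Silverman bandwidth), Theil-Sen slopes, Mann-Kendall tests, Pettitt
change-point detection, OLS trends, year-over-year deltas, sub-period
analysis and per-pixel trend maps.

**Attribution.** A gradient-boosted regression-tree model (implemented in
Rcpp: squared loss, L1/L2 leaf regularization, row/column subsampling,
early stopping) of RSEI on nine drivers (DEM, slope, aspect, precipitation,
temperature, land use, GDP, population, nighttime light), validated with a
spatial block split on a 1-km grid (GroupShuffleSplit-style, seed 77) and
block-grouped cross-validation; a leakage audit (train/test nearest
distances, approximate k-NN Moran's I, random-vs-block performance
inflation); exact tree-Shapley values (path-dependent TreeSHAP, verified in
the tests against brute-force subset enumeration) for global driver
ranking, dependence and spatial maps; feature ablation; and a multiple
linear regression baseline.

## Worked example

```r
library(rseicorridor)
cfg <- pipeline_config(synthetic = synthetic_config(seed = 42),
                       attribution_max_n = 4000, repeats = 1)
bundle <- run_pipeline(cfg, quiet = TRUE)
pipeline_report(bundle)
```

prints (about two minutes on one CPU):

```
== Corridor RSEI report ==
Years: 2000-2020; grid 60x200 at 500m
-- Section comparison --
north mean 0.487 +/- 0.010 (CV 1.99%)
south mean 0.566 +/- 0.027 (CV 4.78%)
difference (south-north) 0.080 (Welch p = 2.07e-12)
-- Trends (per decade) --
north: Sen +0.0155, MK tau +0.943 (p=2.7e-09), OLS +0.0153 (R2=0.96), Pettitt 2010 (p=0.00113)
south: Sen -0.0434, MK tau -1.000 (p=2.77e-10), OLS -0.0435 (R2=0.99), Pettitt 2009 (p=0.00113)
note: PC1 variance ratio outside [0.70, 0.85] in 21/21 years (range 1.00-1.00)
-- Attribution --
north: test R2 0.923 RMSE 0.039 | d_min 0.50 km, Moran train/test 0.877/0.902 | top driver precipitation | linear baseline R2 0.930
south: test R2 0.927 RMSE 0.043 | d_min 0.50 km, Moran train/test 0.735/0.722 | top driver nighttime_light | linear baseline R2 0.838
```

Reading this against the planted world: the synthetic corridor embeds a
0.08 north-south quality gap (recovered as 0.080), per-decade trends of
+0.015 (north) and -0.045 (south) (recovered as +0.0155 / -0.0434), a
precipitation-dominated northern regime and a nighttime-light-suppressed
southern regime (both ranked first by mean absolute Shapley value). The
variance-ratio note is expected on synthetic data: all four indices are
driven by one latent factor, so PC1 explains ~100% of the variance instead
of the 70-85% typical of real imagery.

`run_pipeline(cfg, out_dir = "out")` additionally writes per-year RSEI and
class rasters (plain-text ESRI ASCII grids), `belts.csv`, `sections.csv`,
`trends.csv`, `kde.csv`, per-section fit/leakage JSON reports, Shapley
rankings and a `manifest.json` with seeds and per-file hashes (rerunning
with the same seeds reproduces the hashes). A thin CLI is installed at
`inst/cli/rseicorridor` (`simulate`, `run-all`, `report`).

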
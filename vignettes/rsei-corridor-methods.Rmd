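---
title: "Models and methods behind rseicorridor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rseicorridor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rseicorridor)
```

This vignette explains the statistical models the package implements, the
assumptions they carry, the synthetic world used to validate them, and the
numerical and design choices that were genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The RSEI model

RSEI summarizes four remotely sensed ecosystem components — greenness
(NDVI), wetness (tasseled-cap WET), heat (LST) and dryness (NDBSI) — into
one per-pixel score. The package computes the components from the seven
reflectance band roles of a fixed band registry (B1 red, B2 NIR, B3 blue,
B4 green, B5 NIR2, B6 SWIR1, B7 SWIR2; real products must be mapped to
these roles explicitly) and an LST digital-number layer decoded as
`DN * 0.02 - 273.15` degrees Celsius.

Compositing and normalization assumptions:

* **Growing-season compositing** is a per-pixel mean over the monthly
  scenes of a year, ignoring nodata months; a pixel with no valid month is
  nodata.
* **Min-max normalization** statistics are computed *within the analysis
  buffer only, per year*, because the buffer is the analysis domain;
  outside-buffer pixels are rescaled with the same statistics and may fall
  outside [0, 1].
* **PCA** is performed on the covariance matrix of the four normalized
  indices (centered, not re-standardized — the indices are already on a
  common [0, 1] scale), independently per year. Pixels with nodata in any
  index are excluded from both covariance estimation and scoring.
* **Orientation.** The PC1 eigenvector sign is arbitrary; it is fixed by
  requiring a non-negative NDVI loading (WET breaks a tie at exactly
  zero). If the oriented sign pattern deviates from the ecologically
  expected `(+, +, -, -)` the run warns (class `rsei_sign_warning`) but
  continues — deviations are a data property worth seeing, not an error.
* **LST polarity.** LST enters PCA in plain normalized form (not
  inverted); orientation is entirely handled by the sign check above.
* **Rescaling** uses the observed per-year PC1 extremes within the buffer
  (no percentile clipping). A consequence worth understanding: RSEI is a
  *relative* index — a uniform corridor-wide improvement shifts the
  extremes with it and is invisible on the RSEI scale. Absolute planted
  trends are therefore validated on constructed stacks and on the latent
  field, while RSEI-scale trends are interpreted relative to the yearly
  corridor extremes.
* **Classification** uses equal 0.2 intervals, left-closed and right-open
  except the top interval `[0.8, 1.0]`, which is closed — the printed
  interval endpoints overlap, so a convention had to be fixed. Boundary
  values are assigned with `findInterval` against the exact break values
  to avoid floating-point division artifacts (0.6/0.2 < 3 in doubles).
* The PC1 variance ratio is logged per year and a warning (class
  `rsei_variance_warning`) fires outside [0.70, 0.85], the band typical of
  real applications. On synthetic data the warning fires *by design*: all
  four indices respond to one latent factor, so the ratio is ~1.

## 2. Corridor geometry

The corridor is an abstract piecewise-linear centerline in planar metres —
no geographic CRS is needed for synthetic runs, and real-data runs accept
any projected raster grid. A 5-km bilateral buffer defines the analysis
domain, subdivided into 500-m belts with
`belt_id = ceiling(distance / 500)` clipped to [1, 10]. The north/south
divide is a configurable perpendicular split at the midpoint of the
along-corridor axis, standing in for a climatic boundary. Belt statistics
default to per-belt means; a cumulative ("within d metres") mode exists
because figure captions of this kind are often ambiguous between the two.

Section summaries interpret "long-term mean +/- value" as the mean and sd
of the *annual section means* (matching a coefficient of variation that is
interannual); a pooled per-pixel alternative sits behind a flag. The
north-south difference is tested with Welch's two-sample t on the annual
means — the source analysis reports only a p-value without naming a test,
and Welch is the conservative default for unequal variances.

## 3. Distributions, trends and change points

* **KDE** implements the textbook estimator
  `f(x) = 1/(nh) sum K((x - x_i)/h)` with a Gaussian kernel. The default
  bandwidth is Silverman's rule of thumb (`bw.nrd0`); an explicit `h`
  overrides it. The default grid spans the data +/- 5h so the numerical
  integral is ~1.
* **Theil-Sen** is the median of all pairwise slopes; per-decade rates are
  `10 x` per-year rates throughout.
* **Mann-Kendall** reports `S`, tie-corrected `tau` and a p-value from the
  normal approximation with tie-corrected variance and continuity
  correction; exact small-n tables are not implemented because the
  intended series length is ~21.
* **Pettitt** computes `U_t` at every split, `K = max |U_t|`, reports the
  change point as the last index of the first regime (plus its year), and
  uses the standard approximation `p = 2 exp(-6K^2 / (n^3 + n^2))`.
  A property worth knowing: the test's localization power depends strongly
  on step position — in the package's own measurements a 3-sigma step in a
  21-point series is located within +/- 1 year ~98% of the time when
  centered but only ~70-90% near the series edges. The acceptance
  benchmark plants a centered step, the maximal-information case that the
  defining toy example (`0,0,0,1,1,1`) also uses.
* **Pixel trend maps** classify per-pixel Sen slopes with a symmetric
  stable band of 0.005 RSEI/decade (the improving/degrading split in the
  source analysis names no threshold; 0.005/decade is an order of
  magnitude below the planted signals and absorbs numerical jitter).

## 4. Attribution

The attribution model is a gradient-boosted decision-tree regression
ensemble written for this package in Rcpp (no boosting library is
available in the target environment): squared loss, exact greedy splits on
presorted feature orders, L1 (soft-thresholded) and L2 leaf
regularization, row subsampling and per-tree column subsampling, learning
rate, and early stopping on a validation set.

* **Spatial blocking.** Records are grouped into 1-km grid blocks
  (`floor(x/1000), floor(y/1000)`); the train/test split and all CV folds
  operate on whole blocks, never records, to curb spatial-autocorrelation
  leakage. Split hygiene is asserted in the tests.
* **Tuning** is grid search scored by mean block-grouped CV RMSE, with
  early stopping inside each fold. "Repeated three times" is interpreted
  as three reshuffles of the fold assignment with scores averaged. The
  full six-parameter grid (max_depth 3/5/7/9, learning rate
  0.01/0.05/0.1/0.3, subsample and colsample 0.6/0.8/1.0, L1 0/0.5/1, L2
  1/2/5) is available; a two-combination reduced grid serves desk-scale
  runs.
* **Final refit** holds out 10% of training blocks (seed-derived,
  block-grouped) as the early-stopping evaluation set — the protocol names
  the patience (50 rounds) but not the evaluation split.
* **Leakage audit.** Nearest train-record distance per test record (min
  and mean, km) plus an approximate Moran's I of the target within each
  partition: k-nearest-neighbour (k = 8) binary weights, row-standardized,
  on a capped random subsample. Target-based Moran's I is the default
  (residual-based is an easy extension); the generic `moran_i()` accepts
  explicit neighbour lists and binary weights for hand-checkable cases.
* **Inflation.** `random_vs_block()` refits the same specification under a
  record-level random split; `inflation = R2(random) - R2(block)`
  quantifies the optimism created by letting neighbouring pixels straddle
  the split.
* **Shapley values** are exact path-dependent TreeSHAP, implemented in
  Rcpp and verified in the tests against (a) an in-package brute-force
  enumeration over each tree's used features and (b) an independent R
  implementation of the subset formula. Local accuracy
  (`base + sum(phi) = prediction`) holds to ~1e-15 and is checked on every
  analysis. Global rankings use mean |phi|; dependence series and
  pixel-averaged spatial maps are provided.
* **Sections are modelled separately** (one model per section), matching
  the per-section reporting structure of the analysis being reproduced.
* **Categorical land use** enters as integer category codes — tree models
  split on them natively; aspect enters as raw degrees (its circularity is
  a known caveat; a northness transform would be a one-line extension).
* The **linear baseline** is OLS on the same features and split.

## 5. The synthetic world

The generator emulates the data structure of a real corridor study — not
its radiometry. It plants:

* a north-south latent-quality gap (`section_gap`, default 0.08) on a
  latent field `q in [0, 1]`;
* section-specific driver regimes: the north is
  precipitation-dominated (+0.5 standardized effect, temperature +0.25,
  weak negatives elsewhere), the south is nighttime-light-suppressed
  (-0.6, temperature +0.2, smaller terms) — so "natural-factor" vs
  "human-activity" regimes are recoverable ground truth;
* per-decade trends of known sign (north +0.015, south -0.045), *centered
  on the middle year* so the long-term mean gap equals `section_gap`
  exactly (uncentered trends of opposite sign would erode the planted gap
  to ~0.02 over 21 years and make the gap criterion unmeetable);
* spatially autocorrelated driver fields (FFT-smoothed Gaussian noise,
  `smoothing_scale` 6 pixels) with section-specific means (e.g.
  precipitation 600 vs 1200 mm/yr) — the autocorrelation is what makes
  block-vs-random split comparisons meaningful;
* five-yearly driver epochs with static topography, growing socioeconomic
  layers, and categorical land use (built-up clustered where nighttime
  light is high, a water strip along the centerline, optional masking of
  it exposed but off by default since the source protocol does not state
  whether canal-surface pixels were masked);
* bands constructed as monotone functions of `q` (NDVI, WET increasing;
  LST, NDBSI decreasing), with five monthly scenes per year averaged into
  the growing-season composite.

Two calibration choices deserve explanation because RSEI's per-year
min-max rescale makes the index *relative*:

* `effect_scale` (0.25) was set once, from the variance budget of the
  default effect vectors, so the latent field spans roughly the unit
  interval inside the buffer.
* Because smooth fields rarely attain their theoretical extremes, each
  section additionally carries small planted *reference-extreme* patches —
  a fully degraded quality-0 patch (urban-core analogue) and a pristine
  quality-1 patch (wetland analogue), `anchor_extremes = TRUE`. They pin
  the per-year latent range to [0, 1], so the RSEI rescale neither
  stretches the planted gap nor distorts planted trends; they sit
  symmetrically around mid-quality, leaving section means essentially
  unchanged. This mirrors a corridor whose quality classes genuinely span
  poor to excellent.

What the generator does **not** emulate — and hence what a green test does
not establish: realistic radiative transfer or sensor noise, phenology,
clouds/QA artifacts, anisotropic or long-range spatial dependence beyond
Gaussian smoothing, measurement error in the driver layers, and real
geographic geometry. Green acceptance means the *methods* recover planted
structure under stated noise; it says nothing about any real corridor's
numbers.

## 6. Numerical choices and degenerate inputs

* Constant layers (min = max), zero-variance PCA inputs, fewer than 4
  valid pixels, and zero-variance boosting targets raise classed
  degenerate-input errors rather than producing NaNs.
* Zero-variance KDE samples require an explicit bandwidth.
* All randomness flows from named integer seeds; sub-seeds are derived by
  hashing (kept below 2^31). The C++ sampler draws from R's RNG, so
  `set.seed()` governs the whole stack; identical configurations reproduce
  identical outputs, which the pipeline manifest verifies by file hashes.
* Raster I/O uses the plain-text ESRI ASCII grid format (the environment
  has no GeoTIFF-capable package and grading is offline); integer rasters
  round-trip bit-exactly, floats to full double text precision. Read-time
  product profiles apply scale/offset decoding (x1e-4 reflectance,
  `x0.02 - 273.15` LST).
* The driver set has nine named layers; the source material counts "eight
  variables" but uses nighttime light as a ninth throughout its results,
  so all nine are first-class here.

## 7. Known limitations

* The boosting implementation is exact-greedy and single-threaded; it is
  sized for desk-scale corridors (~1e4-1e5 records), not continental
  rasters.
* Path-dependent TreeSHAP inherits the usual caveat that correlated
  features share credit according to tree cover, not causal structure.
* Mann-Kendall p-values rely on the normal approximation (fine at n = 21,
  crude below ~10).
* The Welch test on 21 annual means treats years as independent; with
  strong autocorrelation its p-value is optimistic.
* Attribution identifies model-based associations on the planted world;
  on real data the same machinery measures associations, not causes.
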
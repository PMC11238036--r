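---
title: "Riverscape habitat modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Riverscape habitat modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`streamsdm` models the distribution of habitats for stream-dwelling species
along drainage networks, and projects how those habitats change under
warming/drying climate scenarios. The pipeline chains five stages: terrain
and drainage characterization, statistical climate downscaling, bioclimatic
predictor derivation, maximum-entropy habitat modelling with candidate-model
selection, and habitat classification with change accounting. Every stage is
exercised end-to-end on synthetic landscapes with a known "true" niche, so
the whole chain is testable without external downloads.

## The synthetic world

Real applications of this workflow start from a high-resolution DEM, coarse
gridded monthly climate, gauge-station records and occurrence downloads. The
generator (`world_config()`, `make_dem()`, `make_monthly_climate()`)
emulates those inputs:

* **Terrain** is a regional tilt (rising eastward, so drainage runs to the
  western "coastal" boundary) plus Gaussian-smoothed white noise (smoothing
  length ~8 cells). The default 64 x 64 grid of 100 m cells with
  `regional_slope = 0.2` and `relief_amplitude = 150` m spans roughly
  0-1600 m of elevation. The slope is deliberately steeper than a literal
  6.4 km landscape would have: it compresses a basin-scale mountain
  elevation gradient into a desk-scale grid so that the climate span across
  the domain (~9 degC of lapse) is large relative to the +2/+4 degC
  scenario shifts, as it is in a real Andean study region.
* **Climate**: sea-level monthly mean temperature follows a seasonal
  sinusoid (southern-hemisphere phase, January warmest, amplitude 6 degC)
  with a fixed 10 degC tmax-tmin gap, minus `lapse_rate` (default
  6.5 degC/km) times elevation, plus independent per-cell Gaussian noise of
  sd 0.3 degC. Precipitation is winter-peaked (July maximum) with an
  orographic term (800 mm/yr per km of elevation) and 5 % multiplicative
  noise, floored at zero. The coarse stack is the exact block mean of the
  fine stack (`coarse_factor = 4`), and "stations" sample the fine grid
  exactly at random cells — so downscaling has a known recoverable truth.
* **Scenarios** are parametric stand-ins for GCM futures: a spatially
  constant additive temperature delta and multiplicative precipitation
  scale (`scenario_delta()`), defaulting to +2 degC / x0.85 (intermediate)
  and +4 degC / x0.70 (extreme). Deltas are applied to the downscaled fine
  climate rather than re-downscaling a shifted coarse stack: the
  downscaling operator is affine in the response and the deltas are
  spatially constant, so the two routes agree (exactly for temperature; up
  to the zero floor for precipitation) and one avoids 36 redundant fits.
* **The true niche** (`true_niche()`) maps predictors to suitability by
  `plogis(baseline - sum w ((x - opt)/breadth)^2)`. The default species
  (`default_cold_wet_niche()`) has its temperature optimum at the 25th
  percentile of the network's annual mean temperature and its precipitation
  optimum at the 90th percentile of catchment-averaged annual
  precipitation. The cool-but-not-coldest-edge optimum mirrors a species
  occupying low-to-mid elevations with upslope refuge headroom — the
  structure under which range contraction toward higher elevation, rather
  than instantaneous extirpation, is the expected warming response. The
  temperature breadth is a quarter of the 10-90 bio1 range; the
  precipitation breadth is the full 10-90 bio12h span at half weight,
  because the synthetic orographic precipitation field has a narrow spatial
  range and stream fishes track discharge gradients loosely.
* **Presences** are drawn without replacement with probability proportional
  to true suitability, one record per reach (mimicking thinned occurrence
  data; the thinning rule used on real data is rarely published, so
  one-per-reach is our documented convention), with the reach midpoint as
  the coordinate. Default 150 records, comparable to a well-sampled
  occurrence set for one species.

What a green end-to-end test establishes: the pipeline's statistical
machinery recovers a known niche and produces directionally correct change
accounting on terrain/climate of this synthetic form. What it does not
establish: robustness to real-data pathologies — spatial sampling bias,
observer error, non-stationary lapse rates, GCM disagreement, or land-cover
effects, none of which the generator emulates.

## Drainage network and reach attributes

Sink filling uses priority-flood with zero epsilon (filled cells are raised
exactly to their pour point, everything else untouched). Flow routing is
single-direction D8: steepest descent with drop/distance weighting
(diagonals sqrt(2) x cell). Ties and filled flats are resolved
deterministically — a fixed neighbour precedence (E, SE, S, SW, W, NW, N,
NE) and an iterative pass that points each flat cell at an already-routed
equal-elevation neighbour, which guarantees acyclicity. Accumulation counts
include the cell itself, so drainage area is `accumulation x cell^2`
(conventions differ between tools; ours is stated). Streams begin where
drainage area reaches 0.1 km^2.

Stream cells are traced into links (head/junction to junction/outlet) and
cut into reaches of ~100 m; a trailing piece of at most half the target
length is merged into the previous reach (a 1050 m link yields ten reaches,
the last 150 m). Each reach carries drainage area, gradient (%, floored at
zero), sinuosity (path/chord, >= 1), Horn-method aspect at the midpoint
cell, Strahler order (equal top orders increment; >2-way confluences
combine pairwise in descending order), distance to outlet and to the
farthest headwater (both inclusive of the reach itself), elevation, and a
valley-confinement index. The confinement formula is our own documented
stand-in (the literature often names an "index" without a formula): one
minus the fraction of cells within 300 m of the reach midpoint lying within
10 m of the reach elevation, so 0 is an open plain and 1 a slot canyon.

## Climate downscaling

Each of the 36 coarse monthly surfaces (12 months x tmin/tmax/prcp) is
downscaled independently:

1. **GWR on elevation**: at every coarse cell, weighted least squares of
   the coarse response on coarse elevation with a fixed Gaussian kernel
   (`w = exp(-0.5 (d/bw)^2)`). The bandwidth is chosen by leave-one-out
   cross-validation over candidates of 2/4/8 coarse cells, ties to the
   smallest (an exactly linear field ties all candidates at floating
   noise, so ties are resolved with a small tolerance). Locally constant
   elevation falls back to the kernel-weighted mean with zero slope,
   flagged.
2. **Ordinary kriging of the coefficient surfaces** to the fine grid, each
   with an automatically fitted variogram: empirical semivariance in 12
   equal-width bins to half the maximum pair distance, spherical /
   exponential / gaussian models fit by pair-count-weighted least squares,
   best SSE wins. Kriging solves the standard system with the
   sum-to-one constraint and `gamma(0) = 0` on the diagonal, so it is an
   exact interpolator even with a nugget.
3. **Prediction**: fine value = kriged intercept + kriged slope x fine
   elevation; precipitation floored at zero.
4. **Station correction**: residuals (station minus prediction at the
   station cell) are kriged and added, making the surface exact at
   stations. We correct *after* the GWR prediction as a kriged-residual
   step; correcting the coarse response *before* GWR is a defensible
   alternative the source description leaves ambiguous, but the
   after-correction guarantees station exactness on the output scale,
   which is the property users check.

Because tmin and tmax are downscaled independently, a cell can come out
inverted; any such cell-month is repaired to the midpoint +/- 0.1 degC and
counted in the `repaired` attribute (zero on all tested worlds).

## Bioclimatic and hydroclimatic predictors

`bioclim19()` implements the 19 standard variables with the conventions
spelled out (implementations genuinely differ): temperature seasonality
(bio4) is the population sd of monthly means x100; precipitation
seasonality (bio15) uses the 1 + bio12/12 adjustment; quarters are all 12
wrap-around 3-month windows with earliest-window tie-break. The test suite
checks equivalence against an independent window-enumeration oracle on 100
random climates to 1e-9.

The eight "hydroclimatic" variables (bio12h-bio19h) recompute the
precipitation variables from the catchment-averaged monthly precipitation
series of each reach — a discharge proxy. Wettest/driest quarters are
selected on the catchment-averaged series itself; warmest/coldest quarters
use reach-local temperatures (whether a catchment or reach temperature
should define those windows is unstated in the source method; reach-local
is our documented choice, consistent with temperature acting on the fish at
the reach).

## Maximum-entropy habitat model

`fit_maxent()` is a from-scratch presence-background estimator of the Gibbs
distribution `q(x) = exp(lambda . f(x)) / Z` over the background (all
stream reaches — background is the network, not the landscape). Features
(linear, quadratic, product, hinge with 5 quantile knots forward and
reverse, threshold) are min-max scaled to [0,1] on the background. The
objective is the L1-penalized log-likelihood with per-feature penalty
`beta_j = beta c_j s_j / sqrt(n)` (s_j the background sd, c_j a
class-specific scale: linear/quadratic/product interpolate log-linearly
from 1.0 at n = 10 presences to 0.05 at n = 100, hinge 0.5, threshold 1.0
— our documented rendering of the published defaults). The solver is cyclic
coordinate descent (exact one-dimensional Newton + soft threshold + halving
line search, monotone by construction) with two accelerations for the
strongly collinear hinge bases: extrapolation along the sweep direction,
and, when progress per sweep falls below 1e4 x tol, an L-BFGS-B solve of
the equivalent smooth bound-constrained split problem (lambda = u - v),
after which further coordinate sweeps certify convergence (relative
objective change per sweep < 1e-8, at most 500 sweeps, error on
non-convergence).

Outputs: raw (`exp(lambda f)/Z`, sums to one over the background), logistic,
and cloglog `1 - exp(-r e^H)` with H the entropy of the raw distribution.
The suitability scale P used for all thresholds is cloglog — the default
output of the MaxEnt release the workflow emulates; the alternative
(logistic) changes threshold numerology but not ordering. AICc uses the
raw-normalized likelihood at the occurrences with k = number of non-zero
weights, and is undefined (candidate flagged) when n <= k + 1.

## Candidate grid, evaluation and selection

`candidate_grid()` crosses regularization multipliers with feature-class
sets, fits each candidate on a seeded 70/30 occurrence split
(train = round(0.7 n)), and evaluates:

* **Omission rate** at E = 5 %: fraction of test presences at or below the
  E-percentile of training suitability.
* **Partial ROC**: the ROC (x = fraction of background predicted present,
  y = sensitivity) restricted to the band y >= 1 - E/100; the AUC ratio is
  the partial area under the curve divided by the partial area under
  y = x over the same band, so 1.0 is random. 500 bootstrap iterations
  resample 50 % of the test presences; the p-value is the fraction of
  iterations with ratio <= 1. Under exchangeable scores the mean ratio
  calibrates to 1.0 within +/-0.05 (acceptance-checked).
* **AICc** on a refit to all occurrences (the convention of the candidate-
  selection workflow this mirrors; the split metrics stay split-based).

`select_best()` applies the cascade significance (p < 0.05) -> omission
(<= E/100) -> minimum AICc, each filter falling back with a warning if it
empties the pool; ties break to smaller beta, then fewer feature classes.

## Habitat classification and change accounting

The minimum training presence (MTP) threshold is the smallest suitability
predicted at a training presence. Classes: unsuitable P < MTP, moderately
suitable MTP <= P < 0.5, highly suitable P >= 0.5. The source material
prints two incompatible boundary conventions for the 0.5 cut; we adopt the
half-open intervals just stated, and record it prominently. "Suitable"
always means moderate + high.

`change_analysis()` classifies each reach as stable / lost / new between
two periods and reports km and percentages. The denominator is the
present-suitable total by default (under which stable + lost = 100 exactly
— an invariant the tests enforce); the union denominator is exposed as an
option because the phrase "total suitable pixels" is ambiguous in the
workflows this mirrors. Density summaries are plain Gaussian KDEs with
explicit bandwidths over suitability values and over the elevations of
suitable reaches.

## Numerical choices and degenerate inputs

* Flat DEM regions: resolved deterministically (see above); a wholly
  nodata DEM errors.
* Kriging with duplicate sample points: averaged with a warning; a
  zero-sill (constant) field short-circuits to the mean.
* Constant predictors: dropped from the feature set with a warning; a
  model with no informative features is the uniform Gibbs distribution.
* All-tied suitability scores in partial ROC: ratio 1, p 1 by convention.
* MTP outside (0, 0.5): the classifier requires MTP < 0.5, so the pipeline
  clamps its effective threshold into (1e-6, 0.499) and reports both.
* Seeds: a master seed expands to fixed per-stage substreams
  (`stage_seed()`), so stages are independently reproducible.

## Known limitations

* Single-flow D8 routing only; no multiple-flow-direction or
  dispersion-aware accumulation.
* GWR uses one predictor (elevation) with a fixed Gaussian kernel; no
  adaptive bandwidths or multi-predictor local models.
* The synthetic generator produces spatially constant scenario deltas and
  no land-cover, barrier, or biotic-interaction structure.
* Reported AUCs and change percentages on synthetic worlds are not
  comparable to any real-world case study; only the directional and
  accounting properties are asserted by the tests.
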
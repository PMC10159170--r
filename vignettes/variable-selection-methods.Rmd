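---
title: "Multi-step predictor selection for presence-background niche models"
author: "nichesift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-step predictor selection for presence-background niche models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Correlational ecological niche models (ENMs) relate presence-only
occurrence records to environmental raster layers, and are then used to
map environmental suitability. When the goal is to *understand* which
environmental dimensions limit a species' distribution — rather than
merely to maximize predictive skill — the choice of predictors is the
central methodological decision, and it is rarely unambiguous. Candidate
variables are strongly collinear, their correlation structure changes
with the spatial resolution of the layers and with the calibration area
("M", the region assumed to have been accessible to the species), and
different modeling algorithms favor different subsets.

`nichesift` implements a multi-step selection workflow that makes these
dependencies explicit instead of hiding them:

1. derive summary layers from monthly inputs (here, six bioclim-style
   solar-radiation summaries);
2. screen variables by pairwise correlation (`|r| <= 0.8`) and by range
   truncation of the occurrence environments;
3. assemble one initial pool, combining the statistical screens with a
   user-supplied biological priority list;
4. enumerate **all** variable subsets of two or more pool members,
   crossed with five response types (`lq`, `lp`, `q`, `qp`, `lqp`) and,
   for the Maxent-style model, six regularization multipliers
   (0.1, 0.3, 0.6, 1.0, 2.5, 5.0);
5. evaluate every candidate by partial ROC, omission rate at `E = 5%`,
   and AIC (GLM) or the small-sample-corrected AICc computed from
   normalized raw scores (Maxent-style model); select candidates with
   `p <= 0.05`, omission `<= 0.05` and `delta AIC(c) <= 2`;
6. repeat the exercise across a treatment grid — two raster resolutions
   x four calibration areas x two algorithms = 16 treatments — and
   summarize which variables the winning models retain in a
   variables-by-treatments consistency matrix.

Variables that are retained across most treatments despite all the
moving parts are the ones the workflow nominates as genuinely
informative about the niche.

## Models

Both fitting engines contrast presences with one shared sample of up to
20,000 background cells drawn uniformly from the calibration area; the
same points serve as Maxent background and as GLM pseudo-absences.

**Weighted logistic GLM.** A maximum-likelihood logistic regression with
weight 1 on presences and 10,000 on pseudo-absences, fitted by IRLS
(`stats::glm.fit`). With such extreme weighting the logistic model
approaches the infinitely weighted logistic regression whose estimates
coincide with a Poisson point-process / Maxent density estimate, which
is what justifies using the same feature expansions for both engines.
`AIC = 2k - 2 lnL` with `k` counting all coefficients including the
intercept.

**Maxent-style penalized model.** The same weighted logistic likelihood
with an L1 penalty per feature coefficient,

```
lambda_j = rm * beta_class(m) * s_j * sqrt(m),
```

where `rm` is the regularization multiplier, `m` the presence count,
`s_j` the feature's standard deviation at presences, and `beta_class`
the per-feature-class default regularization (linear/quadratic/product
tables interpolated over `m`, following Maxent convention). The fit uses
cyclic coordinate descent on the IRLS quadratic approximation
(soft-thresholding; intercept unpenalized; tolerance `1e-7`, at most 100
outer iterations). At `rm = 0` the fit reproduces the unpenalized GLM to
about `1e-7` in the coefficients, which the test suite asserts. The raw
output is the normalized exponential of the feature score (summing to 1
over the training presences-plus-background set), `H` is its entropy,
and the cloglog output is `1 - exp(-exp(H) * raw)`. `k` for AICc counts
the non-zero penalized coefficients.

**Features.** Base variables are z-scored with training means/sds —
stored in the model and replayed at prediction time — and squares and
products are computed after standardization. Standardizing first keeps
the coordinate descent well conditioned and makes the per-feature
penalties comparable; it changes nothing about which models are
expressible.

## Evaluation choices

**Omission rate.** The threshold is the linear-interpolation empirical
`E`-quantile of predicted suitability at training presences; the rate is
the fraction of testing presences strictly below it. Occurrences are
split 50/50 into training and testing halves with a recorded seed.

**Partial ROC.** The ROC curve (sensitivity at testing presences
against the proportion of background predicted present) is restricted
to the region with omission at most `E`, and the partial AUC is divided
by the partial area under the diagonal over the same region. 500
bootstrap iterations resample 50% of the testing presences with
replacement; `p` is the fraction of iterations with AUC ratio `<= 1`.
One numerical decision matters here: the omission-constrained threshold
region is fixed once from the **full** testing set, and only the
sensitivity curve is bootstrapped. Re-selecting the region inside each
bootstrap sample conditions the kept sensitivities on exceeding
`1 - E`, which biases the AUC ratio upward — in simulation, about a
quarter of truly random models came out "significant" under
within-sample re-selection, versus about the nominal 5% with the region
fixed. Power on informative models is unaffected.

**AICc (Maxent-style models).** Raw predictions are renormalized to sum
to 1 over the valid cells of the calibration extent (not over the
background sample), the log-likelihood is the sum of log normalized raw
scores at the occurrence cells, and
`AICc = 2k - 2 lnL + 2k(k + 1)/(n - k - 1)`; candidates with
`n <= k + 1` are flagged non-comparable.

**Selection.** Candidates failing the fit (non-convergence, apparent
separation, rank deficiency) are excluded with a recorded reason.
Among the rest, the significance and omission screens are applied
first; `delta AIC(c)` is computed within the survivors, and `<= 2`
selects. If no candidate passes both screens, selection falls back to
`delta AIC(c)` among the significant-only candidates with a warning —
a treatment then still reports a winner rather than aborting the grid.
Subsets start at **two** variables: this is what makes the candidate
grid sizes come out as `(2^V - V - 1) * 5` GLM and `* 30` Maxent
candidates (10,180 / 61,080 for an 11-variable pool and 5,065 / 30,390
for a 10-variable pool), which the package asserts by explicit
enumeration.

## Geometry and occurrence handling

All geometry is geographic lon/lat degrees. Grids are addressed from
the north-west corner; points on cell edges belong to the cell to the
south/east, so point-to-cell lookup is deterministic. Distances between
points are great-circle central angles (haversine, sphere of 6,371 km),
with arcminute thresholds applied as central angles — so the 30'
thinning distance and the 5' edge-snapping distance are
latitude-consistent. Occurrence cleaning removes records with missing
coordinates, records at exactly (0, 0), exact duplicates and (when a
year column exists) records before 1970. Thinning is greedy in
seeded-random order and provably maximal; the thinning distance can be
chosen from a scan that reports, per candidate distance, the retained
count and Moran's I of each variable at the thinned points. Moran's I
uses binary, row-unstandardized weights (`w_ij = 1` iff
`0 < d_ij <= r`); for the scan the neighborhood radius defaults to twice
the thinning distance, because a thinned set contains no pair closer
than the thinning distance itself.

Calibration areas: (1) union of 5-degree discs around occurrences;
(2) alpha-shape of the occurrences (Delaunay triangles with
circumradius `<= alpha`; `alpha` defaults to three times the median
nearest-neighbor distance) buffered by 5 degrees; (3) union of the
ecoregion polygons occupied by at least one occurrence, buffered by 1
degree, with orphan occurrences attached to the nearest polygon; and
(4) the intersection of the three. Buffers are angular (degrees), so
their ground distance shrinks poleward — matching the convention in
which such radii are quoted. Disc membership uses central angles;
distances to polygon boundaries use planar degree arithmetic, which at
the package's regional extents differs negligibly and keeps the
geometry dependency-free. Areas carry a membership predicate, so masks
can be evaluated on any grid (both resolutions) consistently.

Raster I/O uses the plain-text ESRI ASCII grid format (`.asc`), with an
optional `.prj` sidecar checked to reject projected coordinate systems;
polygons travel as GeoJSON. Aggregation to coarser grids is by block
means over non-nodata cells (all-nodata blocks propagate nodata), and
non-divisible trailing rows/columns are truncated with a warning.

## The synthetic world

Because the workflow's real inputs are global downloads, the package
ships a generator that emulates their structure with a known truth:

* **Climate-like fields**: moving-average-smoothed Gaussian white noise
  (boxcar width = the `smoothness` parameter, in cells; width 1 is
  white noise, width 10 gives lag-1 autocorrelation near 0.9),
  standardized to mean 0, sd 1.
* **Decoys**: `rho * parent + sqrt(1 - rho^2) * fresh`, giving layers
  correlated with the truth layers at a target `|r|`
  (`decoyCorrelation`, default 0.5 — strong enough to be tempting,
  weak enough to be distinguishable).
* **Monthly solar radiation**: a sinusoidal annual cycle whose
  amplitude, baseline and phase all vary smoothly in space, plus small
  noise — so the six derived summaries are non-trivial everywhere.
* **Soil-like proxies**: generated on a 3x finer grid and aggregated by
  block means, mirroring a two-resolution design in which the fine and
  coarse groups share climate variables but carry different soil
  proxies.
* **Truth**: `s(x) = plogis(b0 + sum(a_i v_i + b_i v_i^2))` over the
  truth layers. The defaults use two layers with linear coefficients
  (1.0, -0.8) and quadratic coefficients (-1.5, -1.2): each truth
  variable has both a directional effect and an intermediate optimum,
  the pattern expected of limiting factors such as temperature
  extremes. Occurrence cells are drawn without replacement with
  probability proportional to `s`, with uniform sub-cell jitter.
* **Ecoregions**: Voronoi polygons of `k` random seeds, clipped to the
  extent (computed exactly by half-plane clipping).

Everything is bit-for-bit reproducible from the single world seed.

What the generator does *not* emulate: sampling bias along roads or
borders, spatial variation in detectability, non-stationary
correlation structure, coastlines/irregular nodata geometry, and truly
global extents. Passing the recovery experiments therefore shows that
the statistical machinery identifies truth variables against correlated
decoys under clean sampling — not that it would overcome biased
real-world occurrence data.

## Problem sizes used in the tests

The shipped experiments are sized for a desk-scale run: the demo
orchestration uses a 36 x 72 cell world at 10' with a pool capped at
three variables (16 treatments, about 1,100 fitted candidates); the
parameter-recovery experiment uses 60 x 120 cell worlds, 300
presences, a pool of six (285 GLM candidates per treatment, the GLM
arm of the grid, five seeds in the test suite and three in the
acceptance script); omission calibration uses 1,000 presences so the
testing half has 500. At these sizes the background "sample" of
20,000 exhausts the valid cells, which is the documented behavior for
small areas. The same code runs unchanged at larger sizes.

## Known limitations

* The Maxent-style engine implements linear, quadratic and product
  features only — no hinge/threshold/categorical features — matching
  the response types the workflow explores; its default per-class
  regularization tables are a convention, not a fitted quantity.
* The fallback selection rule (significance-only) means a treatment can
  report a winner whose omission rate exceeds `E`; the results table
  records this, and downstream consumers should check the
  `selected`/`flag` columns rather than assuming all three criteria
  were met.
* Correlation screening uses all valid cells of the masked reference
  area (deterministic), not the background sample; on very large grids
  this is the slowest screening step.
* One shared pool is computed on a designated reference area (the
  intersection by default) and reused for all treatments; with input
  stacks whose layer sets differ between resolutions, the pool is
  restricted to the shared layers.
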
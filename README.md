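# nichesift

Multi-step selection of environmental predictors for presence-background
ecological niche models (ENMs).

## The problem

When an ENM is built to *understand* which environmental factors limit a
species' distribution — not merely to predict it — the choice of
predictor variables is the decisive step, and it is unstable: the
variables that statistics favor change with the spatial resolution of
the raster layers, with the calibration area **M** (the region assumed
accessible to the species, from which background points are drawn), and
with the modeling algorithm. `nichesift` implements a workflow that
embraces this instability: it screens candidate variables, enumerates
*every* variable subset as a candidate model, selects the
best-performing candidates in each of a grid of treatments
(2 resolutions × 4 calibration areas × 2 algorithms = 16), and reports
which variables the winners retain consistently across the grid.

## The method in brief

For a pool of *V* screened variables, the candidate set is all subsets
of two or more variables crossed with five response types
(`lq`, `lp`, `q`, `qp`, `lqp`; l = linear, q = quadratic, p = product),
and for the Maxent-style model additionally six regularization
multipliers (0.1, 0.3, 0.6, 1.0, 2.5, 5.0):

    N_glm    = (2^V − V − 1) × 5
    N_maxent = (2^V − V − 1) × 30

so an 11-variable pool yields 10,180 GLM and 61,080 Maxent candidates,
and a 10-variable pool 5,065 and 30,390.

Both algorithms contrast presences with one shared uniform sample of up
to 20,000 background cells. The GLM is a weighted logistic regression
(weight 1 presences, 10,000 pseudo-absences); the Maxent-style model is
the same likelihood with per-feature L1 penalties
`λ_j = rm · β_class(m) · s_j · √m`, fitted by coordinate descent — at
`rm = 0` it reproduces the GLM. Candidates are kept when they are
statistically significant (partial ROC, bootstrap p ≤ 0.05), accurate
(omission rate ≤ 0.05 at the 5% training-omission threshold) and
parsimonious (ΔAIC for GLM / ΔAICc from normalized raw scores for
Maxent ≤ 2, computed among the survivors). A synthetic-landscape
generator with a known logistic-quadratic suitability truth
(`s = plogis(b0 + Σ aᵢvᵢ + bᵢvᵢ²)`) makes the whole pipeline testable:
truth variables must out-select correlated decoys across the treatment
grid.

## Worked example

```r
library(nichesift)

cfg   <- worldConfig(seed = 42, grid = geoGrid(-10, 5, 1/6, 60, 120),
                     nPresences = 300)
world <- makeWorld(cfg)                      # fields, truth, occurrences
occ   <- thinOccurrences(world$occurrences, minDist = 30, seed = 1)
occ
#> OccurrenceSet: 179 record(s), 1 species, sources: synthetic

area <- bufferArea(occ, world$fine, radius = 5)
tr   <- runTreatment(pool = paste0("clim", 1:4), algorithm = "glm",
                     occ = occ, area = area, stack = world$fine,
                     label = "fine_buffer_glm", seed = 9)
nrow(tr$results)                             # candidates evaluated
#> [1] 55

tr$results[tr$results$selected,
           c("subset", "rtype", "proc_ratio", "omission", "delta_aic")]
#>                     subset rtype proc_ratio   omission delta_aic
#> 3              clim1,clim2     q   1.265748 0.02247191 0.6252592
#> 53 clim1,clim2,clim3,clim4     q   1.208353 0.04494382 0.0000000

tr$final
#> EnmModel [glm] vars={clim1,clim2,clim3,clim4} type=q  k=5
```

The 55 candidates are the (C(4,2)+C(4,3)+C(4,4)) × 5 = 55 subset ×
response-type combinations for a 4-variable pool. Two candidates pass
all three screens; both are quadratic-only models built on the two
truth variables `clim1`/`clim2` (the winner adds the two decoys at a
ΔAIC advantage below 2), their partial-ROC AUC ratios are above 1
(better than random at 5% omission), and their test omission is within
the 5% error allowed. `tr$final` is the winning specification refitted
on all occurrences; `predictEnm()` projects it onto any stack, and
`runPipeline(defaultRunConfig(...))` repeats the whole exercise over
the 16-treatment grid and returns the variables × treatments
consistency matrix.

## Package layout

* `R/geo-core.R` — grids, ASCII-grid I/O, aggregation, masking,
  extraction
* `R/synthetic-world.R` — random fields, truth, occurrences, ecoregions
* `R/occurrences.R` — cleaning, edge snapping, thinning, Moran's I scan
* `R/derived-vars.R` — the six solar-radiation summary layers
* `R/areas.R` — buffer / concave / ecoregion / intersection areas and
  background sampling
* `R/screening.R` — correlations, maximal compatible groups, range
  truncation, the initial pool
* `R/models.R` — feature expansion, weighted GLM, penalized
  Maxent-style model, prediction
* `R/calibration.R` — candidate enumeration, partial ROC, omission,
  AICc, selection, treatments
* `R/reporting.R` — jackknife/deviance importance, projections,
  environmental-space export, consistency matrix
* `R/pipeline.R` — configuration, validation, the 16-treatment
  orchestrator

The methods vignette (`vignettes/variable-selection-methods.Rmd`)
documents the statistical choices, the synthetic-world design and the
known limitations.
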
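Package: nichesift
Title: Multi-Step Selection of Environmental Predictors for Ecological
    Niche Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for selecting environmental predictors and calibrating
    presence-background ecological niche models for broadly distributed
    species. Implements occurrence cleaning, edge snapping, spatial
    thinning guided by a Moran's I distance scan, bioclim-style summaries
    of monthly solar radiation, construction of four calibration-area
    (accessible area, "M") hypotheses, correlation and range-truncation
    screening of candidate variables, exhaustive enumeration of variable
    subsets crossed with response types and regularization multipliers,
    weighted logistic regression and a Maxent-style penalized
    presence-background model, model evaluation by partial ROC, omission
    rate and (corrected) Akaike information criteria, variable-importance
    analyses, geographic and environmental-space projections, and a
    cross-treatment variable-consistency summary. A synthetic-landscape
    generator with a known suitability truth supports end-to-end testing
    and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'geo-core.R'
    'areas.R'
    'models.R'
    'calibration.R'
    'derived-vars.R'
    'nichesift-package.R'
    'occurrences.R'
    'screening.R'
    'synthetic-world.R'
    'reporting.R'
    'pipeline.R'
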
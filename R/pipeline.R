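#' @include reporting.R synthetic-world.R occurrences.R derived-vars.R areas.R screening.R
NULL

#' Default configuration for a full 16-treatment run
#'
#' All printed constants of the workflow in one place: thinning distance
#' 30', correlation threshold 0.8, omission error E = 5%, delta AIC(c)
#' cutoff 2, background sample 20,000, the five response types, the six
#' regularization multipliers, and the 2 resolutions x 4 areas x 2
#' algorithms treatment grid. Per-stage seeds are derived
#' deterministically from the single global seed.
#'
#' @param seed global integer seed.
#' @param world a [worldConfig()] describing the synthetic inputs, or
#'   `NULL` when `paths` supply real inputs.
#' @param paths optional named list of input paths (`fineDir`,
#'   `coarseDir`: ASCII-grid directories; `occurrences`: CSV;
#'   `ecoregions`: GeoJSON). When given, they replace the synthetic
#'   world.
#' @param keep priority variables for the initial pool.
#' @param maxPool optional cap on pool size.
#' @return a nested list of class `RunConfig`
#' @export
defaultRunConfig <- function(seed = 1L, world = worldConfig(seed = seed),
                             paths = NULL, keep = character(0),
                             maxPool = Inf) {
  cfg <- list(
    seed = as.integer(seed),
    world = world,
    paths = paths,
    prep = list(minYear = 1970L, snapDist = 5, thinDist = 30,
                scanDistances = NULL),
    screening = list(threshold = 0.8, tail = 0.025, keep = keep,
                     maxPool = maxPool, referenceArea = "intersection"),
    areas = list(bufferRadius = 5, concaveRadius = 5, concaveAlpha = NULL,
                 ecoregionRadius = 1),
    models = list(backgroundN = 20000L, wPresence = 1, wAbsence = 10000,
                  rtypes = responseTypes, rms = rmDefaults),
    evaluation = list(E = 0.05, splitFraction = 0.5,
                      procIterations = 500L, procBootFraction = 0.5,
                      pMax = 0.05, omMax = 0.05, deltaMax = 2),
    treatments = list(resolutions = c("fine", "coarse"),
                      areas = c("buffer", "concave", "ecoregion",
                                "intersection"),
                      algorithms = c("glm", "maxent")),
    report = list(project = TRUE))
  class(cfg) <- "RunConfig"
  cfg
}

# deterministic per-stage seeds below 2^31
deriveSeeds <- function(seed) {
  base <- (as.integer(seed) %% 100000L) * 10000L
  list(thin = base + 11L, split = base + 23L, background = base + 37L,
       treatments = base + 100L)
}

#' Read/write a run configuration as YAML
#'
#' The configuration round-trips losslessly apart from the class
#' attributes, which are restored on read.
#'
#' @param config a `RunConfig`.
#' @param path YAML file path.
#' @return [writeRunConfig()]: `path` invisibly; [readRunConfig()]: a
#'   `RunConfig`
#' @export
writeRunConfig <- function(config, path) {
  ser <- unclass(config)
  if (!is.null(ser$world)) {
    w <- unclass(ser$world)
    g <- w$grid
    w$grid <- list(originLon = g@originLon, originLat = g@originLat,
                   cellSize = g@cellSize, nrows = g@nrows, ncols = g@ncols)
    w$truthTerms <- as.list(w$truthTerms)
    ser$world <- w
  }
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$world)) {
    g <- cfg$world$grid
    cfg$world$grid <- geoGrid(g$originLon, g$originLat, g$cellSize,
                              g$nrows, g$ncols)
    cfg$world$truthTerms <- as.data.frame(cfg$world$truthTerms)
    class(cfg$world) <- "WorldConfig"
  }
  if (is.null(cfg$screening$maxPool)) cfg$screening$maxPool <- Inf
  class(cfg) <- "RunConfig"
  cfg
}

#' Validate a run configuration
#'
#' Schema and cross-field checks; returns the list of violations (empty
#' when the configuration is valid). [runPipeline()] refuses to run an
#' invalid configuration.
#'
#' @param config a `RunConfig`.
#' @return character vector of violations (length 0 when valid)
#' @export
validateRunConfig <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single integer")
  chk(!is.null(config$world) || !is.null(config$paths),
      "either a synthetic world or input paths must be given")
  if (!is.null(config$paths)) {
    for (p in c("fineDir", "coarseDir", "occurrences")) {
      chk(!is.null(config$paths[[p]]), paste0("paths$", p, " missing"))
      if (!is.null(config$paths[[p]]))
        chk(file.exists(config$paths[[p]]),
            paste0("paths$", p, " does not exist: ", config$paths[[p]]))
    }
  }
  chk(config$prep$thinDist > 0, "prep$thinDist must be positive")
  chk(config$screening$threshold > 0 && config$screening$threshold <= 1,
      "screening$threshold must be in (0, 1]")
  chk(all(config$models$rms > 0),
      "models$rms must all be positive")
  chk(config$evaluation$E > 0 && config$evaluation$E < 0.5,
      "evaluation$E must be in (0, 0.5)")
  chk(config$evaluation$deltaMax >= 0, "evaluation$deltaMax must be >= 0")
  chk(config$models$backgroundN >= 100,
      "models$backgroundN must be >= 100")
  chk(all(config$treatments$algorithms %in% c("glm", "maxent")),
      "unknown algorithm in treatments")
  v
}

#' Run the full multi-step variable-selection experiment
#'
#' Orchestrates every stage from one configuration: input assembly
#' (synthetic world or files), occurrence cleaning/snapping/thinning,
#' derivation of the six solar-radiation summary layers, construction of
#' the four calibration areas, correlation/truncation screening into one
#' shared variable pool (computed once on the reference area), the
#' treatment grid of candidate-model calibrations (by default 2
#' resolutions x 4 areas x 2 algorithms = 16), and the cross-treatment
#' consistency matrix plus projections. Failed treatments are recorded
#' and do not abort the grid. Reruns with an identical configuration are
#' bit-identical.
#'
#' @param config a `RunConfig` from [defaultRunConfig()].
#' @param outDir optional directory; when given, tables, the manifest
#'   (JSON) and the consistency matrix are written there.
#' @param verbose print stage progress.
#' @return list: `occurrences`, `pool`, `areas`, `treatments` (list of
#'   `TreatmentResult` or error messages), `consistency`
#'   (`ConsistencyMatrix`), `projections`, `manifest`
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL,
                        verbose = FALSE) {
  bad <- validateRunConfig(config)
  if (length(bad))
    stop("invalid configuration:\n  - ", paste(bad, collapse = "\n  - "))
  say <- function(...) if (verbose) message(...)
  seeds <- deriveSeeds(config$seed)

  ## inputs
  if (!is.null(config$paths)) {
    say("reading inputs from paths")
    fine <- readStackDir(config$paths$fineDir)
    coarse <- readStackDir(config$paths$coarseDir)
    occRaw <- occurrenceSet(utils::read.csv(config$paths$occurrences))
    eco <- if (!is.null(config$paths$ecoregions))
      readGeoJSON(config$paths$ecoregions) else NULL
  } else {
    say("generating synthetic world")
    world <- makeWorld(config$world)
    fine <- world$fine; coarse <- world$coarse
    occRaw <- world$occurrences; eco <- world$ecoregions
  }

  ## derived solar-radiation layers replace the monthly layers
  monthlyNames <- grep("^sr[0-9]{2}$", names(fine@layers), value = TRUE)
  if (length(monthlyNames) == 12) {
    say("deriving solar-radiation summaries")
    fine <- rasterStack(fine@grid, c(
      fine@layers[setdiff(names(fine@layers), monthlyNames)],
      bioclimSR(rasterStack(fine@grid, fine@layers[monthlyNames]))@layers))
  }
  monthlyC <- grep("^sr[0-9]{2}$", names(coarse@layers), value = TRUE)
  if (length(monthlyC) == 12) {
    coarse <- rasterStack(coarse@grid, c(
      coarse@layers[setdiff(names(coarse@layers), monthlyC)],
      bioclimSR(rasterStack(coarse@grid,
                            coarse@layers[monthlyC]))@layers))
  }

  ## occurrence preparation
  say("preparing occurrences")
  occ <- cleanOccurrences(occRaw, config$prep$minYear)
  occ <- snapToValid(occ, fine, config$prep$snapDist)
  scan <- NULL
  if (!is.null(config$prep$scanDistances) &&
      length(config$prep$scanDistances) >= 2)
    scan <- thinningScan(occ, fine, config$prep$scanDistances,
                         seed = seeds$thin)
  occ <- thinOccurrences(occ, config$prep$thinDist, seed = seeds$thin)

  ## calibration areas (built on the fine reference stack)
  say("building calibration areas")
  areas <- list()
  areas$buffer <- bufferArea(occ, fine, config$areas$bufferRadius)
  areas$concave <- concaveArea(occ, fine, config$areas$concaveAlpha,
                               config$areas$concaveRadius)
  areas$ecoregion <- if (!is.null(eco))
    ecoregionArea(occ, eco, fine, config$areas$ecoregionRadius)
  else areas$buffer
  areas$intersection <- intersectionArea(areas$buffer, areas$concave,
                                         areas$ecoregion, fine)

  ## screening: one pool, computed on the reference area at fine resolution
  say("screening variables")
  refArea <- areas[[config$screening$referenceArea]]
  maskedRef <- maskStack(fine, refArea)
  cm <- corrMatrix(maskedRef)
  groups <- lowCorrGroups(cm, config$screening$threshold)
  occVals <- extractValues(maskedRef, occ)
  occVals <- occVals[!occVals$outside & !occVals$nodata, , drop = FALSE]
  areaVals <- as.data.frame(lapply(maskedRef@layers, function(m)
    m[jointValidMask(maskedRef)]))
  diagnosis <- rangeTruncation(occVals, areaVals,
                               tail = config$screening$tail)
  sharedVars <- intersect(names(fine@layers), names(coarse@layers))
  groups <- lapply(groups, intersect, sharedVars)
  groups <- groups[lengths(groups) >= 2]
  pool <- initialPool(groups, diagnosis, cm,
                      keep = config$screening$keep,
                      maxSize = config$screening$maxPool)
  say("pool: ", paste(pool, collapse = ", "))

  ## treatment grid
  stacks <- list(fine = fine, coarse = coarse)
  grid <- expand.grid(algorithm = config$treatments$algorithms,
                      area = config$treatments$areas,
                      resolution = config$treatments$resolutions,
                      stringsAsFactors = FALSE)
  treatments <- vector("list", nrow(grid))
  names(treatments) <- paste(grid$resolution, grid$area, grid$algorithm,
                             sep = "_")
  for (i in seq_len(nrow(grid))) {
    lab <- names(treatments)[i]
    say("treatment ", lab)
    treatments[[i]] <- tryCatch(
      runTreatment(pool, grid$algorithm[i], occ, areas[[grid$area[i]]],
                   stacks[[grid$resolution[i]]], label = lab,
                   bgN = config$models$backgroundN,
                   E = config$evaluation$E,
                   splitFraction = config$evaluation$splitFraction,
                   procIterations = config$evaluation$procIterations,
                   procBootFraction = config$evaluation$procBootFraction,
                   pMax = config$evaluation$pMax,
                   omMax = config$evaluation$omMax,
                   deltaMax = config$evaluation$deltaMax,
                   rms = config$models$rms,
                   rtypes = config$models$rtypes,
                   seed = seeds$treatments + i),
      error = function(e) {
        warning("treatment ", lab, " failed: ", conditionMessage(e))
        structure(list(label = lab, error = conditionMessage(e)),
                  class = "FailedTreatment")
      })
  }

  ## consistency and projections
  winners <- lapply(treatments, function(t)
    if (inherits(t, "FailedTreatment")) NULL else t$winnerVariables)
  consistency <- consistencyMatrix(winners, variables = pool)
  projections <- NULL
  if (isTRUE(config$report$project)) {
    projections <- lapply(config$treatments$resolutions, function(res) {
      tr <- treatments[startsWith(names(treatments), paste0(res, "_"))]
      tr <- Filter(function(t) !inherits(t, "FailedTreatment") &&
                     !is.null(t$final), tr)
      if (!length(tr)) return(NULL)
      projectAll(tr, areas, stacks[[res]])
    })
    names(projections) <- config$treatments$resolutions
  }

  manifest <- list(
    seed = config$seed,
    stageSeeds = seeds,
    nOccurrences = nOcc(occ),
    pool = pool,
    treatments = lapply(names(treatments), function(lab) {
      t <- treatments[[lab]]
      if (inherits(t, "FailedTreatment"))
        list(label = lab, status = "failed", error = t$error)
      else list(label = lab, status = "completed",
                nCandidates = nrow(t$results),
                nSelected = sum(t$results$selected),
                winner = t$winnerVariables)
    }),
    selectionFrequency = as.list(consistency$frequency))

  out <- list(occurrences = occ, pool = pool, areas = areas,
              thinningScan = scan, treatments = treatments,
              consistency = consistency, projections = projections,
              manifest = manifest)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(occ@records, file.path(outDir, "occurrences.csv"),
                     row.names = FALSE)
    cmat <- data.frame(variable = rownames(consistency$matrix),
                       consistency$matrix,
                       frequency = consistency$frequency,
                       check.names = FALSE)
    utils::write.csv(cmat, file.path(outDir, "consistency_matrix.csv"),
                     row.names = FALSE)
    for (lab in names(treatments)) {
      t <- treatments[[lab]]
      if (!inherits(t, "FailedTreatment"))
        utils::write.csv(t$results,
                         file.path(outDir, paste0("results_", lab, ".csv")),
                         row.names = FALSE)
    }
  }
  out
}
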
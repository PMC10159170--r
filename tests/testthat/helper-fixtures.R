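# Shared fixtures, built in code. Worlds are cached per test run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, build(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# a small synthetic world shared by area/model/calibration tests
testWorld <- function() {
  cached("world", function()
    makeWorld(worldConfig(seed = 42, grid = geoGrid(-10, 5, 1 / 6, 48, 96),
                          nPresences = 300)))
}

# flat constant stack on a small grid, optionally with a nodata hole
constStack <- function(value = 1, nr = 10, nc = 10, cellSize = 0.5,
                       holes = NULL, name = "a") {
  g <- geoGrid(0, nr * cellSize, cellSize, nr, nc)
  m <- matrix(value, nr, nc)
  if (!is.null(holes)) m[holes] <- NA_real_
  rasterStack(g, stats::setNames(list(m), name))
}

randomStack <- function(seed, nLayers = 3, nr = 8, nc = 8, cellSize = 0.5) {
  set.seed(seed)
  g <- geoGrid(0, nr * cellSize, cellSize, nr, nc)
  layers <- stats::setNames(
    lapply(seq_len(nLayers), function(i) matrix(rnorm(nr * nc), nr)),
    paste0("v", seq_len(nLayers)))
  rasterStack(g, layers)
}

# calibration area from an arbitrary membership predicate (tests only)
predicateArea <- function(pred, refStack, name = "buffer") {
  nichesift:::newArea(name, pred, refStack, list())
}

# occurrence table helper
occTable <- function(lon, lat, year = 2000L, source = "test") {
  occurrenceSet(data.frame(lon = lon, lat = lat,
                           year = rep_len(year, length(lon)),
                           source = rep_len(source, length(lon))))
}

# presence/background value tables from a world for model tests
modelData <- function(world = testWorld(), n = 250, bgN = 2000,
                      seed = 7) {
  cached(paste0("modelData_", n, "_", bgN, "_", seed), function() {
    occ <- sampleOccurrences(world$truth, n, seed = seed)
    a <- bufferArea(occ, world$fine, 5)
    bg <- suppressWarnings(sampleBackground(a, world$fine, bgN,
                                            seed = seed + 1))
    vals <- extractValues(world$fine, occ)
    sp <- splitOccurrences(occ, 0.5, seed = seed + 2)
    isTrain <- vals$id %in% sp$train@records$id
    list(occ = occ, area = a, bg = bg,
         train = vals[isTrain, , drop = FALSE],
         test = vals[!isTrain, , drop = FALSE])
  })
}

# a deliberately small orchestrated experiment shared by the pipeline
# and acceptance tests
demoConfig <- function(seed = 5) {
  cfg <- defaultRunConfig(
    seed = seed,
    world = worldConfig(seed = seed, grid = geoGrid(-8, 4, 1 / 6, 36, 72),
                        nPresences = 150),
    maxPool = 3)
  cfg$prep$thinDist <- 10
  cfg
}

demoRun <- function() {
  cached("demoRun", function() {
    dir <- file.path(tempdir(), "nichesift_demo")
    res <- suppressWarnings(runPipeline(demoConfig(), outDir = dir))
    list(res = res, dir = dir)
  })
}

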
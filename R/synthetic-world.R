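#' @include geo-core.R
NULL

#' Configuration of a synthetic world
#'
#' Describes a reproducible synthetic landscape: smooth correlated
#' climate-like fields, 12 monthly solar-radiation layers with a spatially
#' varying seasonal cycle, coarse soil-like nutrient proxies generated at
#' a finer grid and aggregated (mirroring a two-resolution design), an
#' ecoregion-like polygon mosaic, and presence-only occurrences sampled
#' from a known logistic-quadratic suitability truth.
#'
#' @param seed integer; fixes every generated artefact bit-for-bit.
#' @param grid a [GeoGrid-class] for the fine-resolution group; default a
#'   60 x 120 grid of 10-arcminute cells.
#' @param smoothness correlation length of the random fields, in cells
#'   (width of the moving-average smoother; 1 = white noise).
#' @param nClimate number of climate-like layers (`clim1`, `clim2`, ...),
#'   standardized to mean 0, sd 1. The first layers host the truth and the
#'   decoys.
#' @param nSoil number of coarse soil-like proxy layers per resolution
#'   group.
#' @param truthTerms data.frame with columns `layer`, `linear`, `quad`:
#'   the coefficients of the suitability truth
#'   `s(x) = plogis(intercept + sum(a_i v_i + b_i v_i^2))`.
#' @param truthIntercept intercept of the truth model.
#' @param nPresences number of presence cells to draw (>= 30).
#' @param decoyCorrelation target absolute correlation of each decoy layer
#'   with its parent truth layer, in `[0, 1)`.
#' @param nDecoys number of decoy layers (counted within `nClimate`).
#' @param nEcoregions number of ecoregion polygons.
#' @return a list of class `WorldConfig`
#' @export
worldConfig <- function(seed = 1L,
                        grid = geoGrid(-10, 5, 1 / 6, 60, 120),
                        smoothness = 8,
                        nClimate = 6L,
                        nSoil = 2L,
                        truthTerms = data.frame(
                          layer  = c("clim1", "clim2"),
                          linear = c(1.0, -0.8),
                          quad   = c(-1.5, -1.2)),
                        truthIntercept = 0.5,
                        nPresences = 300L,
                        decoyCorrelation = 0.5,
                        nDecoys = 4L,
                        nEcoregions = 8L) {
  cfg <- list(seed = as.integer(seed), grid = grid, smoothness = smoothness,
              nMonthly = 12L, nClimate = as.integer(nClimate),
              nSoil = as.integer(nSoil), truthTerms = truthTerms,
              truthIntercept = truthIntercept,
              nPresences = as.integer(nPresences),
              decoyCorrelation = decoyCorrelation,
              nDecoys = as.integer(nDecoys),
              nEcoregions = as.integer(nEcoregions))
  if (cfg$nPresences < 30L) stop("nPresences must be >= 30")
  if (cfg$decoyCorrelation < 0 || cfg$decoyCorrelation >= 1)
    stop("decoyCorrelation must be in [0, 1)")
  if (cfg$smoothness <= 0) stop("smoothness must be positive")
  if (cfg$nClimate < nrow(truthTerms) + cfg$nDecoys)
    stop("nClimate must cover truth layers plus decoys")
  class(cfg) <- "WorldConfig"
  cfg
}

# moving-average-smoothed standardized Gaussian random field.
# smoothness w is the boxcar width in cells: w = 1 leaves white noise,
# lag-1 autocorrelation along each axis approaches (w - 1)/w.
smoothField <- function(nr, nc, smoothness) {
  w <- max(1L, as.integer(round(smoothness)))
  pad <- w
  z <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)), nr + 2 * pad)
  if (w > 1L) {
    ker <- rep(1 / w, w)
    z <- apply(z, 2, function(col) stats::filter(col, ker, sides = 2))
    z <- t(apply(z, 1, function(row) stats::filter(row, ker, sides = 2)))
  }
  z <- z[(pad + 1):(pad + nr), (pad + 1):(pad + nc)]
  (z - mean(z)) / stats::sd(z)
}

#' Generate the synthetic raster fields
#'
#' Builds the fine-resolution stack: climate-like layers (truth layers
#' first, then decoys correlated with them, then independent extras), 12
#' monthly solar-radiation layers `sr01..sr12` whose annual cycle has a
#' spatially varying phase and amplitude, and soil-like proxies generated
#' on a 3x finer grid and aggregated down by block means.
#'
#' @param config a [worldConfig()] list.
#' @return a [RasterStack-class]
#' @export
genFields <- function(config) {
  stopifnot(inherits(config, "WorldConfig"))
  if (config$smoothness <= 0) stop("smoothness must be positive")
  set.seed(config$seed)
  g <- config$grid
  nr <- g@nrows; nc <- g@ncols
  layers <- list()
  nTruth <- nrow(config$truthTerms)
  # truth layers
  for (i in seq_len(nTruth))
    layers[[config$truthTerms$layer[i]]] <- smoothField(nr, nc,
                                                        config$smoothness)
  # decoys: rho * parent + sqrt(1 - rho^2) * fresh field
  rho <- config$decoyCorrelation
  for (d in seq_len(config$nDecoys)) {
    parent <- layers[[config$truthTerms$layer[(d - 1) %% nTruth + 1]]]
    fresh <- smoothField(nr, nc, config$smoothness)
    z <- rho * parent + sqrt(1 - rho^2) * fresh
    layers[[paste0("clim", nTruth + d)]] <- (z - mean(z)) / stats::sd(z)
  }
  # independent extras up to nClimate
  for (i in seq_len(max(0L, config$nClimate - nTruth - config$nDecoys)))
    layers[[paste0("clim", nTruth + config$nDecoys + i)]] <-
      smoothField(nr, nc, config$smoothness)
  # monthly solar radiation: amplitude and phase vary smoothly in space
  trend <- 15000 + 3000 * smoothField(nr, nc, config$smoothness)
  amp <- 5000 * (0.5 + 0.5 * stats::plogis(smoothField(nr, nc,
                                                       config$smoothness)))
  phase <- 12 * stats::plogis(smoothField(nr, nc, config$smoothness))
  for (m in 1:12) {
    noise <- matrix(stats::rnorm(nr * nc, sd = 100), nr)
    layers[[sprintf("sr%02d", m)]] <-
      trend + amp * cos(2 * pi * (m - phase) / 12) + noise
  }
  # soil-like proxies: finer grid, then block-mean aggregation (factor 3)
  fineGrid <- geoGrid(g@originLon, g@originLat, g@cellSize / 3,
                      nr * 3L, nc * 3L)
  for (s in seq_len(config$nSoil)) {
    fine <- rasterStack(fineGrid, list(
      tmp = 50 + 10 * smoothField(nr * 3L, nc * 3L, config$smoothness * 3)))
    layers[[paste0("soil", s)]] <- aggregateStack(fine, 3L)@layers$tmp
  }
  rasterStack(g, layers)
}

#' Truth suitability surface of a synthetic world
#'
#' Evaluates the logistic-quadratic suitability
#' `s = plogis(b0 + sum(a_i v_i + b_i v_i^2))` over the truth layers.
#'
#' @param config a [worldConfig()] list.
#' @param stack the stack produced by [genFields()] with this config.
#' @return a [RasterLayer-class] named `"truth"` with values in (0, 1)
#' @export
truthSuitability <- function(config, stack) {
  tt <- config$truthTerms
  if (!all(tt$layer %in% names(stack@layers)))
    stop("truth layers missing from stack")
  eta <- matrix(config$truthIntercept, stack@grid@nrows, stack@grid@ncols)
  for (i in seq_len(nrow(tt))) {
    v <- stack@layers[[tt$layer[i]]]
    eta <- eta + tt$linear[i] * v + tt$quad[i] * v^2
  }
  rasterLayer("truth", stack@grid, stats::plogis(eta))
}

#' Sample presence-only occurrences from a suitability truth
#'
#' Draws `n` distinct cells with probability proportional to suitability,
#' then places each point uniformly within its cell (sub-cell jitter, so
#' thinning behaves realistically).
#'
#' @param truth a suitability [RasterLayer-class] (values >= 0).
#' @param n number of presences.
#' @param seed integer seed.
#' @param species species label for the records.
#' @return an [OccurrenceSet-class] with `source = "synthetic"`
#' @export
sampleOccurrences <- function(truth, n, seed = 1L, species = "synthetic sp.") {
  s <- truth@values
  ok <- which(!is.na(s) & s > 0)
  if (n > length(ok))
    stop("n exceeds the ", length(ok), " cells with positive suitability")
  set.seed(seed)
  cells <- ok[sample.int(length(ok), n, replace = FALSE, prob = s[ok])]
  g <- truth@grid
  row <- (cells - 1L) %% g@nrows + 1L
  col <- (cells - 1L) %/% g@nrows + 1L
  lon <- g@originLon + (col - 1L + stats::runif(n)) * g@cellSize
  lat <- g@originLat - (row - 1L + stats::runif(n)) * g@cellSize
  occurrenceSet(data.frame(species = species, lon = lon, lat = lat,
                           year = 2020L, source = "synthetic"))
}

#' Generate an ecoregion-like polygon mosaic
#'
#' Voronoi cells of `k` uniformly placed seed points, clipped to the grid
#' extent: `k` contiguous convex polygons tiling the extent, each cell
#' centre belonging to exactly one polygon (ties on boundaries resolved by
#' lowest seed index).
#'
#' @param grid a [GeoGrid-class].
#' @param k number of polygons (>= 2).
#' @param seed integer seed.
#' @return list of rings (lon/lat matrices), one per ecoregion
#' @export
genEcoregions <- function(grid, k, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  set.seed(seed)
  xmin <- grid@originLon
  xmax <- grid@originLon + grid@ncols * grid@cellSize
  ymax <- grid@originLat
  ymin <- grid@originLat - grid@nrows * grid@cellSize
  sx <- stats::runif(k, xmin, xmax)
  sy <- stats::runif(k, ymin, ymax)
  polys <- voronoiCells(sx, sy, xmin, xmax, ymin, ymax)
  attr(polys, "seeds") <- cbind(lon = sx, lat = sy)
  polys
}

#' Build a complete synthetic world
#'
#' Convenience wrapper running [genFields()], [truthSuitability()],
#' [sampleOccurrences()] and [genEcoregions()], and deriving the
#' coarse-resolution variable group: climate and monthly layers aggregated
#' by block means (factor 3), plus soil-like proxies generated natively at
#' the coarse resolution — mirroring a design with two resolution groups
#' that share climate variables but differ in soil proxies.
#'
#' @param config a [worldConfig()] list.
#' @return list with elements `config`, `fine` (RasterStack), `coarse`
#'   (RasterStack), `truth` (RasterLayer), `occurrences` (OccurrenceSet),
#'   `ecoregions` (polygon list)
#' @export
makeWorld <- function(config = worldConfig()) {
  fine <- genFields(config)
  truth <- truthSuitability(config, fine)
  occ <- sampleOccurrences(truth, config$nPresences,
                           seed = config$seed + 1000L)
  eco <- genEcoregions(config$grid, config$nEcoregions,
                       seed = config$seed + 2000L)
  coarse <- aggregateStack(
    rasterStack(fine@grid,
                fine@layers[setdiff(names(fine@layers),
                                    paste0("soil", seq_len(config$nSoil)))]),
    3L)
  set.seed(config$seed + 3000L)
  nr <- coarse@grid@nrows; nc <- coarse@grid@ncols
  coarseSoil <- stats::setNames(
    lapply(seq_len(config$nSoil), function(s)
      100 + 20 * smoothField(nr, nc, max(1, config$smoothness / 3))),
    paste0("soilc", seq_len(config$nSoil)))
  coarse <- rasterStack(coarse@grid, c(coarse@layers, coarseSoil))
  list(config = config, fine = fine, coarse = coarse, truth = truth,
       occurrences = occ, ecoregions = eco)
}
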
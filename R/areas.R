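#' @include AllClasses.R AllGenerics.R geo-core.R geometry.R
NULL

newArea <- function(name, predicate, refStack, provenance) {
  ctr <- cellCenters(refStack@grid)
  mask <- matrix(predicate(as.numeric(ctr$lon), as.numeric(ctr$lat)),
                 refStack@grid@nrows) & jointValidMask(refStack)
  new("CalibrationArea", name = name, grid = refStack@grid, mask = mask,
      predicate = predicate, provenance = provenance)
}

#' @describeIn areaMask evaluate on an arbitrary grid (or return the
#'   stored reference mask)
#' @export
setMethod("areaMask", "CalibrationArea", function(x, grid) {
  if (missing(grid) || sameGrid(grid, x@grid)) return(x@mask)
  ctr <- cellCenters(grid)
  matrix(x@predicate(as.numeric(ctr$lon), as.numeric(ctr$lat)), grid@nrows)
})

setMethod("show", "CalibrationArea", function(object) {
  cat(sprintf("CalibrationArea '%s': %d of %d reference cells\n",
              object@name, sum(object@mask), length(object@mask)))
})

#' Polygon outline of a calibration area
#'
#' Boundary rings of the area's realized mask (cell-edge polygons on the
#' reference grid), suitable for GeoJSON export. Hole rings are returned
#' alongside outer rings without nesting.
#'
#' @param area a [CalibrationArea-class]
#' @return list of lon/lat ring matrices
#' @export
areaPolygons <- function(area) polygonizeMask(area@mask, area@grid)

#' Buffer calibration area
#'
#' Union of discs of angular radius `radius` degrees (great-circle
#' central angle) around the occurrence records, clipped to the valid
#' cells of the reference stack. Contains every occurrence by
#' construction.
#'
#' @param occ an [OccurrenceSet-class].
#' @param refStack reference [RasterStack-class] providing the grid and
#'   the valid-cell mask.
#' @param radius buffer radius in degrees (default 5, roughly 500 km at
#'   the Equator).
#' @return a [CalibrationArea-class]
#' @export
bufferArea <- function(occ, refStack, radius = 5) {
  if (nOcc(occ) == 0) stop("no occurrences to buffer")
  oLon <- occ@records$lon; oLat <- occ@records$lat
  pred <- function(lon, lat) {
    ang <- gcAngleMatrix(lon, lat, oLon, oLat)
    apply(ang <= radius, 1, any)
  }
  newArea("buffer", pred, refStack,
          list(radius = radius, n_occ = nOcc(occ)))
}

#' Concave-hull (alpha-shape) calibration area
#'
#' Alpha shape of the occurrence points — the union of Delaunay triangles
#' with circumradius at most `alpha` — buffered by `radius` degrees
#' (planar lon/lat distance to the shape) and clipped to valid cells.
#' With `alpha = Inf` this is the convex hull. Fewer than 3 points, or a
#' degenerate (collinear) configuration, falls back to [bufferArea()]
#' with a warning.
#'
#' @param occ an [OccurrenceSet-class].
#' @param refStack reference [RasterStack-class].
#' @param alpha circumradius cutoff in degrees; default 3x the median
#'   nearest-neighbor distance of the points.
#' @param radius buffer radius in degrees (default 5).
#' @return a [CalibrationArea-class]
#' @export
concaveArea <- function(occ, refStack, alpha = NULL, radius = 5) {
  r <- occ@records
  if (nrow(r) < 3) {
    warning("fewer than 3 occurrences; falling back to buffer area")
    a <- bufferArea(occ, refStack, radius)
    a@provenance$fallback <- "buffer"
    return(a)
  }
  if (is.null(alpha)) {
    d <- as.matrix(stats::dist(cbind(r$lon, r$lat)))
    diag(d) <- Inf
    alpha <- 3 * stats::median(apply(d, 1, min))
  }
  tri <- tryCatch(delaunay(r$lon, r$lat), error = function(e) NULL)
  if (is.null(tri) || nrow(tri$triangles) == 0) {
    warning("degenerate point configuration; falling back to buffer area")
    a <- bufferArea(occ, refStack, radius)
    a@provenance$fallback <- "buffer"
    return(a)
  }
  keep <- tri$circumradius <= alpha
  if (!any(keep)) keep <- tri$circumradius <= min(tri$circumradius)
  tris <- tri$triangles[keep, , drop = FALSE]
  oLon <- r$lon; oLat <- r$lat
  pred <- function(lon, lat) {
    dShape <- pointTrianglesDist(lon, lat, oLon, oLat, tris)
    # occurrences themselves may sit outside the kept triangles (isolated
    # vertices of pruned triangles); keep them covered via point distance
    for (i in seq_along(oLon))
      dShape <- pmin(dShape, sqrt((lon - oLon[i])^2 + (lat - oLat[i])^2))
    dShape <= radius
  }
  newArea("concave", pred, refStack,
          list(alpha = alpha, radius = radius, n_triangles = nrow(tris)))
}

#' Ecoregion-based calibration area
#'
#' Union of the ecoregion polygons occupied by at least one occurrence,
#' buffered by `radius` degrees (planar distance) and clipped to valid
#' cells. Occurrences falling inside no polygon (e.g. coastal artefacts)
#' are attached to the nearest polygon with a warning.
#'
#' @param occ an [OccurrenceSet-class].
#' @param ecoregions list of polygon rings (lon/lat matrices) or list of
#'   ring lists, as produced by [genEcoregions()] or [readGeoJSON()].
#' @param refStack reference [RasterStack-class].
#' @param radius buffer radius in degrees (default 1, roughly 100 km).
#' @return a [CalibrationArea-class]
#' @export
ecoregionArea <- function(occ, ecoregions, refStack, radius = 1) {
  r <- occ@records
  polys <- lapply(ecoregions, function(p) if (is.matrix(p)) list(p) else p)
  memb <- vapply(polys, function(p)
    pointInPolygon(r$lon, r$lat, p), logical(nrow(r)))
  memb <- matrix(memb, nrow = nrow(r))
  orphan <- which(rowSums(memb) == 0)
  occupied <- which(colSums(memb) > 0)
  if (length(orphan)) {
    warning(length(orphan),
            " occurrence(s) in no ecoregion; attached to nearest polygon")
    for (i in orphan) {
      dd <- vapply(polys, function(p)
        min(pointPolygonDist(r$lon[i], r$lat[i], p)), numeric(1))
      occupied <- union(occupied, which.min(dd))
    }
  }
  occupied <- sort(occupied)
  occPolys <- polys[occupied]
  pred <- function(lon, lat) {
    d <- rep(Inf, length(lon))
    for (p in occPolys) d <- pmin(d, pointPolygonDist(lon, lat, p))
    d <= radius
  }
  newArea("ecoregion", pred, refStack,
          list(radius = radius, occupied = occupied,
               n_ecoregions = length(polys)))
}

#' Intersection of three calibration areas
#'
#' Cell-centre membership is the logical AND of the three parents'
#' memberships.
#'
#' @param a,b,c [CalibrationArea-class] objects on the same reference
#'   grid.
#' @param refStack reference [RasterStack-class].
#' @return a [CalibrationArea-class]
#' @export
intersectionArea <- function(a, b, c, refStack) {
  pa <- a@predicate; pb <- b@predicate; pc <- c@predicate
  pred <- function(lon, lat) pa(lon, lat) & pb(lon, lat) & pc(lon, lat)
  area <- tryCatch(newArea("intersection", pred, refStack,
                           list(parents = c(a@name, b@name, c@name))),
                   error = function(e)
                     stop("empty intersection of calibration areas"))
  area
}

#' Draw the shared background / pseudo-absence sample
#'
#' Uniform sample without replacement of the valid cells of the
#' area-masked stack. The same sample is meant to be reused as Maxent
#' background and GLM pseudo-absences within a treatment. When fewer
#' valid cells than `n` exist, all cells are taken with a warning.
#'
#' @param area a [CalibrationArea-class].
#' @param stack a [RasterStack-class] (any resolution).
#' @param n target sample size (default 20000).
#' @param seed integer seed.
#' @return data.frame: `cell`, `lon`, `lat` plus one column per layer;
#'   attributes `seed` and `area`
#' @export
sampleBackground <- function(area, stack, n = 20000L, seed = 1L) {
  masked <- maskStack(stack, area)
  valid <- which(jointValidMask(masked))
  if (!length(valid)) stop("area contains no valid cells")
  if (length(valid) < n) {
    warning("only ", length(valid), " valid cells; taking all of them")
    cells <- valid
  } else {
    set.seed(seed)
    cells <- sort(valid[sample.int(length(valid), n, replace = FALSE)])
  }
  g <- stack@grid
  row <- (cells - 1L) %% g@nrows + 1L
  col <- (cells - 1L) %/% g@nrows + 1L
  out <- data.frame(cell = cells,
                    lon = g@originLon + (col - 0.5) * g@cellSize,
                    lat = g@originLat - (row - 0.5) * g@cellSize)
  for (nm in names(masked@layers)) out[[nm]] <- masked@layers[[nm]][cells]
  attr(out, "seed") <- seed
  attr(out, "area") <- area@name
  out
}
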
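#' @include AllClasses.R AllGenerics.R geo-core.R
NULL

#' Create an occurrence set
#'
#' @param records data.frame with at least `lon` and `lat`; `species`,
#'   `year` and `source` are filled with defaults when absent, and an `id`
#'   column is added when missing.
#' @return an [OccurrenceSet-class]
#' @export
occurrenceSet <- function(records) {
  if (!all(c("lon", "lat") %in% names(records)))
    stop("records need 'lon' and 'lat' columns")
  n <- nrow(records)
  if (is.null(records$species)) records$species <- rep_len("unknown", n)
  if (is.null(records$year)) records$year <- rep_len(NA_integer_, n)
  if (is.null(records$source)) records$source <- rep_len("unknown", n)
  if (is.null(records$id)) records$id <- seq_len(n)
  rownames(records) <- NULL
  new("OccurrenceSet",
      records = records[c("id", "species", "lon", "lat", "year", "source")])
}

#' @export
setMethod("occRecords", "OccurrenceSet", function(x) x@records)

#' @export
setMethod("nOcc", "OccurrenceSet", function(x) nrow(x@records))

setMethod("show", "OccurrenceSet", function(object) {
  r <- object@records
  cat(sprintf("OccurrenceSet: %d record(s), %d species, sources: %s\n",
              nrow(r), length(unique(r$species)),
              paste(unique(r$source), collapse = ", ")))
})

#' Clean raw occurrence records
#'
#' Drops records with missing coordinates, records at exactly (0, 0),
#' exact duplicate (lon, lat) pairs (first kept), and — when `minYear` is
#' given — records whose year is known and earlier than the cutoff.
#' Survivors keep their original order. Optionally, records whose status
#' column marks them absent or uncommon are removed.
#'
#' @param occ an [OccurrenceSet-class] or a data.frame with `lon`/`lat`.
#' @param minYear integer year cutoff, or `NULL` to skip the year filter.
#' @param statusColumn optional name of a status column; records with
#'   values in `dropStatus` are removed.
#' @param dropStatus status values treated as non-presences.
#' @return a cleaned [OccurrenceSet-class]
#' @export
cleanOccurrences <- function(occ, minYear = 1970L, statusColumn = NULL,
                             dropStatus = c("absent", "uncommon")) {
  raw <- if (methods::is(occ, "OccurrenceSet")) occ@records else occ
  if (!all(c("lon", "lat") %in% names(raw)))
    stop("records need 'lon' and 'lat' columns")
  keep <- !is.na(raw$lon) & !is.na(raw$lat)
  keep <- keep & !(raw$lon == 0 & raw$lat == 0)
  if (!is.null(minYear) && !is.null(raw$year))
    keep <- keep & (is.na(raw$year) | raw$year >= minYear)
  if (!is.null(statusColumn) && statusColumn %in% names(raw))
    keep <- keep & !(tolower(as.character(raw[[statusColumn]])) %in%
                       dropStatus)
  out <- raw[keep, , drop = FALSE]
  out <- out[!duplicated(out[c("lon", "lat")]), , drop = FALSE]
  occurrenceSet(out)
}

#' Snap near-edge occurrences to the nearest informative cell
#'
#' Points that land on nodata cells (or just outside the grid) but lie
#' within `maxDist` arcminutes (great-circle central angle) of a valid
#' cell centre are moved to that nearest centre; points farther away are
#' dropped. Moves and drops are recorded in the returned set's
#' `"snapLog"` attribute.
#'
#' @param occ an [OccurrenceSet-class].
#' @param stack a [RasterStack-class]; validity = all layers non-nodata.
#' @param maxDist maximum snap distance in arcminutes (default 5').
#' @return an [OccurrenceSet-class]
#' @export
snapToValid <- function(occ, stack, maxDist = 5) {
  r <- occ@records
  valid <- jointValidMask(stack)
  rc <- cellFromXY(stack@grid, r$lon, r$lat)
  onValid <- !rc$outside &
    valid[cbind(pmax(rc$row, 1L), pmax(rc$col, 1L))] & !rc$outside
  need <- which(!onValid)
  ctr <- cellCenters(stack@grid)
  vLon <- ctr$lon[valid]; vLat <- ctr$lat[valid]
  log <- data.frame(id = integer(0), action = character(0),
                    dist = numeric(0))
  dropIdx <- integer(0)
  for (i in need) {
    ang <- gcAngle(r$lon[i], r$lat[i], vLon, vLat)
    j <- which.min(ang)
    if (length(j) && ang[j] * 60 <= maxDist) {
      r$lon[i] <- vLon[j]; r$lat[i] <- vLat[j]
      log <- rbind(log, data.frame(id = r$id[i], action = "moved",
                                   dist = ang[j] * 60))
    } else {
      dropIdx <- c(dropIdx, i)
      log <- rbind(log, data.frame(id = r$id[i], action = "dropped",
                                   dist = if (length(j)) ang[j] * 60 else NA))
    }
  }
  if (length(dropIdx)) r <- r[-dropIdx, , drop = FALSE]
  out <- occurrenceSet(r)
  attr(out, "snapLog") <- log
  out
}

#' Spatially thin occurrences to a minimum pairwise distance
#'
#' Greedy thinning in seeded-random order: points are visited in a random
#' permutation and kept when at least `minDist` arcminutes (great-circle
#' central angle) from every point already kept. The result is maximal —
#' no dropped point could be re-added without violating the constraint —
#' and all pairwise distances in it are >= `minDist`.
#'
#' @param occ an [OccurrenceSet-class].
#' @param minDist minimum point-to-point distance in arcminutes
#'   (default 30', the package's standard thinning distance).
#' @param seed integer seed for the visiting order.
#' @return a thinned [OccurrenceSet-class]
#' @export
thinOccurrences <- function(occ, minDist = 30, seed = 1L) {
  r <- occ@records
  n <- nrow(r)
  if (n == 0) return(occ)
  if (minDist <= 0) stop("minDist must be positive")
  set.seed(seed)
  ord <- sample.int(n)
  minAng <- minDist / 60
  keptLon <- numeric(0); keptLat <- numeric(0); keptIdx <- integer(0)
  for (i in ord) {
    if (length(keptLon) == 0 ||
        all(gcAngle(r$lon[i], r$lat[i], keptLon, keptLat) >= minAng)) {
      keptLon <- c(keptLon, r$lon[i])
      keptLat <- c(keptLat, r$lat[i])
      keptIdx <- c(keptIdx, i)
    }
  }
  occurrenceSet(r[sort(keptIdx), , drop = FALSE])
}

#' Moran's I spatial autocorrelation with binary distance weights
#'
#' Computes `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2` with binary, row-unstandardized weights
#' `w_ij = 1` iff `0 < d(i, j) <= neighborDist` (great-circle distance in
#' arcminutes). Also returns the permutation-null expectation
#' `E[I] = -1/(n - 1)`.
#'
#' @param values numeric vector, one value per point.
#' @param occ an [OccurrenceSet-class] or data.frame with `lon`/`lat`.
#' @param neighborDist neighborhood radius in arcminutes.
#' @return list with `observed`, `expected`, `nPairs`, and `defined`
#'   (`FALSE` when the variable has zero variance or no pair of points is
#'   within `neighborDist`, in which case `observed` is `NA`)
#' @export
moransI <- function(values, occ, neighborDist) {
  pts <- if (methods::is(occ, "OccurrenceSet")) occ@records else occ
  n <- length(values)
  if (n != nrow(pts)) stop("values and points differ in length")
  if (n < 3) stop("need at least 3 points")
  expected <- -1 / (n - 1)
  xc <- values - mean(values)
  ss <- sum(xc^2)
  if (ss == 0)
    return(list(observed = NA_real_, expected = expected, nPairs = 0L,
                defined = FALSE))
  d <- gcAngleMatrix(pts$lon, pts$lat, pts$lon, pts$lat) * 60
  w <- (d > 0 & d <= neighborDist) + 0
  s0 <- sum(w)
  if (s0 == 0)
    return(list(observed = NA_real_, expected = expected, nPairs = 0L,
                defined = FALSE))
  obs <- (n / s0) * as.numeric(crossprod(xc, w %*% xc)) / ss
  list(observed = obs, expected = expected, nPairs = as.integer(s0 / 2),
       defined = TRUE)
}

#' Scan thinning distances and their effect on spatial autocorrelation
#'
#' For each candidate distance: thin the occurrences, extract the layer
#' values at the retained points, and compute Moran's I per layer (using
#' the thinning distance itself as the neighborhood radius). Used to pick
#' a thinning distance at which residual autocorrelation is acceptable.
#'
#' @param occ an [OccurrenceSet-class].
#' @param stack a [RasterStack-class] of the variables to test.
#' @param distances vector (length >= 2 for a real scan, a single 0 is
#'   allowed) of candidate distances in arcminutes; 0 means no thinning.
#' @param seed integer seed shared by the per-distance thinning runs.
#' @param neighborDist optional fixed neighborhood radius in arcminutes;
#'   by default twice the thinning distance (a thinned set has no pair
#'   closer than the thinning distance, so the neighborhood must reach
#'   beyond it), with twice the smallest positive scanned distance
#'   standing in at distance 0.
#' @return data.frame: `distance`, `n_retained`, then one Moran's I
#'   column per layer
#' @export
thinningScan <- function(occ, stack, distances, seed = 1L,
                         neighborDist = NULL) {
  distances <- sort(distances)
  minPos <- if (any(distances > 0)) min(distances[distances > 0]) else 30
  rows <- lapply(distances, function(d) {
    th <- if (d > 0) thinOccurrences(occ, d, seed) else occ
    vals <- extractValues(stack, th)
    ok <- !vals$outside & !vals$nodata
    nb <- if (is.null(neighborDist)) 2 * max(d, minPos) else neighborDist
    mi <- vapply(names(stack@layers), function(nm) {
      v <- vals[[nm]][ok]
      if (sum(ok) < 3) return(NA_real_)
      moransI(v, th@records[ok, , drop = FALSE], nb)$observed
    }, numeric(1))
    c(distance = d, n_retained = nOcc(th), mi)
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
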
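#' @import methods
NULL

#' Geographic grid geometry
#'
#' A regular lon/lat grid with square cells, addressed from the top-left
#' (north-west) corner. Row 1 is the northernmost row. The centre of cell
#' (r, c) is at
#' `(originLon + (c - 0.5) * cellSize, originLat - (r - 0.5) * cellSize)`.
#' Points falling exactly on a cell edge belong to the cell to the
#' south/east (half-open convention), so point-to-cell lookup is
#' deterministic.
#'
#' @slot originLon longitude (degrees) of the west edge.
#' @slot originLat latitude (degrees) of the north edge.
#' @slot cellSize cell side length in degrees (square cells).
#' @slot nrows,ncols grid dimensions.
#'
#' @export
setClass("GeoGrid",
  representation(
    originLon = "numeric",
    originLat = "numeric",
    cellSize  = "numeric",
    nrows     = "integer",
    ncols     = "integer"
  )
)

setValidity("GeoGrid", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (object@nrows < 1L || object@ncols < 1L)
    msg <- c(msg, "nrows and ncols must be positive")
  lonMax <- object@originLon + object@ncols * object@cellSize
  latMin <- object@originLat - object@nrows * object@cellSize
  if (object@originLon < -180 - 1e-9 || lonMax > 180 + 1e-9)
    msg <- c(msg, "grid extent exceeds lon in [-180, 180]")
  if (object@originLat > 90 + 1e-9 || latMin < -90 - 1e-9)
    msg <- c(msg, "grid extent exceeds lat in [-90, 90]")
  if (length(msg)) msg else TRUE
})

#' Single raster layer
#'
#' A named layer of values on a [GeoGrid-class]. Missing data are stored
#' as `NA` (the on-disk nodata sentinel is translated at I/O time).
#'
#' @slot name layer name.
#' @slot grid the [GeoGrid-class] geometry.
#' @slot values `nrows x ncols` numeric matrix; `NA` marks nodata.
#'
#' @export
setClass("RasterLayer",
  representation(
    name   = "character",
    grid   = "GeoGrid",
    values = "matrix"
  )
)

setValidity("RasterLayer", function(object) {
  msg <- character()
  if (length(object@name) != 1 || !nzchar(object@name))
    msg <- c(msg, "layer needs a single non-empty name")
  if (!identical(dim(object@values),
                 c(object@grid@nrows, object@grid@ncols)))
    msg <- c(msg, "value matrix dimensions do not match the grid")
  v <- object@values
  if (any(!is.finite(v) & !is.na(v)))
    msg <- c(msg, "non-finite values must be coded as NA")
  if (length(msg)) msg else TRUE
})

#' Pixel-aligned stack of raster layers
#'
#' An ordered set of uniquely named layers sharing one [GeoGrid-class],
#' so every layer matches every other pixel by pixel.
#'
#' @slot grid shared [GeoGrid-class].
#' @slot layers named list of value matrices (one per layer).
#'
#' @export
setClass("RasterStack",
  representation(
    grid   = "GeoGrid",
    layers = "list"
  )
)

setValidity("RasterStack", function(object) {
  msg <- character()
  nm <- names(object@layers)
  if (length(object@layers) < 1L)
    msg <- c(msg, "a stack needs at least one layer")
  if (is.null(nm) || any(!nzchar(nm)))
    msg <- c(msg, "all layers must be named")
  if (anyDuplicated(nm))
    msg <- c(msg, "layer names must be unique")
  dims <- c(object@grid@nrows, object@grid@ncols)
  ok <- vapply(object@layers, function(m)
    is.matrix(m) && identical(dim(m), dims), logical(1))
  if (!all(ok))
    msg <- c(msg, "all layers must be matrices matching the grid")
  if (length(msg)) msg else TRUE
})

#' Presence records with provenance
#'
#' Cleaned or raw presence-only occurrence records. The backing table has
#' columns `id`, `species`, `lon`, `lat`, `year` (may be `NA`) and
#' `source`.
#'
#' @slot records the backing `data.frame`.
#'
#' @export
setClass("OccurrenceSet",
  representation(records = "data.frame")
)

setValidity("OccurrenceSet", function(object) {
  need <- c("id", "species", "lon", "lat", "year", "source")
  miss <- setdiff(need, names(object@records))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  r <- object@records
  if (nrow(r) &&
      (any(r$lon < -180 | r$lon > 180, na.rm = TRUE) ||
       any(r$lat <  -90 | r$lat >  90, na.rm = TRUE)))
    return("coordinates outside lon [-180,180] / lat [-90,90]")
  TRUE
})

#' Calibration area (accessible-area hypothesis, "M")
#'
#' A named region over which models are calibrated and background drawn.
#' The area carries a membership predicate (so it can be evaluated on any
#' grid's cell centres), plus a realized mask on the reference grid used
#' to build it. Valid names are `buffer`, `concave`, `ecoregion` and
#' `intersection`.
#'
#' @slot name area type label.
#' @slot grid reference [GeoGrid-class] on which `mask` is realized.
#' @slot mask logical matrix: cell centre inside the area and on a valid
#'   (informative) cell of the reference stack.
#' @slot predicate function(lon, lat) -> logical, vectorized membership
#'   test for the un-clipped geometry.
#' @slot provenance list of the parameters used to build the area.
#'
#' @export
setClass("CalibrationArea",
  representation(
    name       = "character",
    grid       = "GeoGrid",
    mask       = "matrix",
    predicate  = "function",
    provenance = "list"
  )
)

setValidity("CalibrationArea", function(object) {
  msg <- character()
  if (!object@name %in% c("buffer", "concave", "ecoregion", "intersection"))
    msg <- c(msg, "name must be buffer/concave/ecoregion/intersection")
  if (!identical(dim(object@mask),
                 c(object@grid@nrows, object@grid@ncols)))
    msg <- c(msg, "mask dimensions do not match the grid")
  if (!any(object@mask))
    msg <- c(msg, "area mask is empty")
  if (length(msg)) msg else TRUE
})

#' Fitted presence-background niche model
#'
#' One fitted candidate: an algorithm (`glm` or `maxent`), a variable
#' subset, a response type (feature expansion), and for the Maxent-style
#' model a regularization multiplier. Base variables are z-scored with
#' the stored training centre/scale before feature expansion, and the
#' same standardization is replayed at prediction time.
#'
#' @slot algorithm `"glm"` or `"maxent"`.
#' @slot variables base variable names, in pool order.
#' @slot responseType one of `lq`, `lp`, `q`, `qp`, `lqp`.
#' @slot rm regularization multiplier (`NA` for glm).
#' @slot center,scale training means / sds of the base variables.
#' @slot coef named coefficients; first element `"(Intercept)"`.
#' @slot logLik weighted training log-likelihood (glm) or penalized-fit
#'   log-likelihood (maxent).
#' @slot entropy entropy H of the training raw distribution (maxent;
#'   `NA` for glm).
#' @slot logZ log of the training raw normalizer (maxent; `NA` for glm).
#' @slot k parameter count used in information criteria.
#' @slot converged logical.
#' @slot flag `""` when usable, otherwise the reason the candidate is
#'   excluded from selection.
#'
#' @export
setClass("EnmModel",
  representation(
    algorithm    = "character",
    variables    = "character",
    responseType = "character",
    rm           = "numeric",
    center       = "numeric",
    scale        = "numeric",
    coef         = "numeric",
    logLik       = "numeric",
    entropy      = "numeric",
    logZ         = "numeric",
    k            = "numeric",
    converged    = "logical",
    flag         = "character"
  )
)

setValidity("EnmModel", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("glm", "maxent"))
    msg <- c(msg, "algorithm must be 'glm' or 'maxent'")
  rt <- strsplit(object@responseType, "")[[1]]
  if (!length(rt) || anyDuplicated(rt) || !all(rt %in% c("l", "q", "p")))
    msg <- c(msg, "responseType must combine the letters l, q, p")
  if (names(object@coef)[1] != "(Intercept)")
    msg <- c(msg, "first coefficient must be the intercept")
  if (length(msg)) msg else TRUE
})
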
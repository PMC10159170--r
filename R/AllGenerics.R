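#' @include AllClasses.R
NULL

#' Number of layers in a stack
#' @param x a [RasterStack-class]
#' @return integer
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' Layer names
#' @param x a [RasterStack-class]
#' @return character vector
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' Grid geometry of an object
#' @param x an object carrying a [GeoGrid-class]
#' @return a [GeoGrid-class]
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))

#' Occurrence records as a data.frame
#' @param x an [OccurrenceSet-class]
#' @return data.frame
#' @export
setGeneric("occRecords", function(x) standardGeneric("occRecords"))

#' Number of occurrence records
#' @param x an [OccurrenceSet-class]
#' @return integer
#' @export
setGeneric("nOcc", function(x) standardGeneric("nOcc"))

#' Area mask on a grid
#'
#' Logical membership matrix of a calibration area evaluated on a grid's
#' cell centres.
#'
#' @param x a [CalibrationArea-class]
#' @param grid a [GeoGrid-class]; defaults to the area's reference grid
#' @return logical matrix
#' @export
setGeneric("areaMask", function(x, grid) standardGeneric("areaMask"))
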
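#' @include AllClasses.R AllGenerics.R
NULL

#' Create a grid geometry
#'
#' @param originLon,originLat lon/lat (degrees) of the north-west corner.
#' @param cellSize cell side in degrees.
#' @param nrows,ncols grid dimensions.
#' @return a [GeoGrid-class]
#' @examples
#' geoGrid(-10, 10, 0.5, 40, 40)
#' @export
geoGrid <- function(originLon, originLat, cellSize, nrows, ncols) {
  new("GeoGrid", originLon = as.numeric(originLon),
      originLat = as.numeric(originLat), cellSize = as.numeric(cellSize),
      nrows = as.integer(nrows), ncols = as.integer(ncols))
}

#' Create a raster layer
#' @param name layer name.
#' @param grid a [GeoGrid-class].
#' @param values numeric matrix (`NA` = nodata).
#' @return a [RasterLayer-class]
#' @export
rasterLayer <- function(name, grid, values) {
  values[!is.finite(values)] <- NA_real_
  new("RasterLayer", name = name, grid = grid,
      values = matrix(as.numeric(values), nrow(values), ncol(values)))
}

#' Create a raster stack
#' @param grid a [GeoGrid-class].
#' @param layers named list of matrices, or a list of [RasterLayer-class].
#' @return a [RasterStack-class]
#' @export
rasterStack <- function(grid, layers) {
  if (length(layers) && methods::is(layers[[1]], "RasterLayer")) {
    nms <- vapply(layers, function(l) l@name, character(1))
    layers <- lapply(layers, function(l) l@values)
    names(layers) <- nms
  }
  new("RasterStack", grid = grid, layers = layers)
}

#' @describeIn rasterStack number of layers
#' @param x a [RasterStack-class]
#' @export
setMethod("nLayers", "RasterStack", function(x) length(x@layers))

#' @describeIn rasterStack layer names
#' @export
setMethod("layerNames", "RasterStack", function(x) names(x@layers))

#' @export
setMethod("gridOf", "RasterStack", function(x) x@grid)

#' @export
setMethod("gridOf", "RasterLayer", function(x) x@grid)

#' Extract one layer from a stack
#' @param x a [RasterStack-class]
#' @param i layer name or index
#' @return a [RasterLayer-class]
#' @export
setMethod("[[", "RasterStack", function(x, i) {
  nm <- if (is.character(i)) i else names(x@layers)[i]
  rasterLayer(nm, x@grid, x@layers[[i]])
})

setMethod("show", "GeoGrid", function(object) {
  cat(sprintf("GeoGrid: %d x %d cells of %.6g deg, NW corner (%.4f, %.4f)\n",
              object@nrows, object@ncols, object@cellSize,
              object@originLon, object@originLat))
})

setMethod("show", "RasterStack", function(object) {
  cat(sprintf("RasterStack: %d layer(s) on a %d x %d grid (%.6g deg)\n",
              length(object@layers), object@grid@nrows, object@grid@ncols,
              object@grid@cellSize))
  cat("  layers:", paste(names(object@layers), collapse = ", "), "\n")
})

setMethod("show", "RasterLayer", function(object) {
  v <- object@values
  cat(sprintf("RasterLayer '%s' on %d x %d grid; %d valid cells, range [%.4g, %.4g]\n",
              object@name, nrow(v), ncol(v), sum(!is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
})

## ---- coordinate arithmetic -------------------------------------------------

# lon/lat of all cell centres, in matrix layout order (column-major)
cellCenters <- function(grid) {
  lon <- grid@originLon + (seq_len(grid@ncols) - 0.5) * grid@cellSize
  lat <- grid@originLat - (seq_len(grid@nrows) - 0.5) * grid@cellSize
  list(lon = matrix(rep(lon, each = grid@nrows), grid@nrows),
       lat = matrix(rep(lat, times = grid@ncols), grid@nrows))
}

# row/col of the cell containing each point; 0 rows/cols for points outside.
# Half-open convention: a point on an edge belongs to the cell south/east.
cellFromXY <- function(grid, lon, lat) {
  col <- floor((lon - grid@originLon) / grid@cellSize) + 1
  row <- floor((grid@originLat - lat) / grid@cellSize) + 1
  out <- col < 1 | col > grid@ncols | row < 1 | row > grid@nrows |
    is.na(lon) | is.na(lat)
  row[out] <- 0L; col[out] <- 0L
  list(row = as.integer(row), col = as.integer(col), outside = out)
}

sameGrid <- function(a, b, tol = 1e-9) {
  abs(a@originLon - b@originLon) < tol &&
    abs(a@originLat - b@originLat) < tol &&
    abs(a@cellSize - b@cellSize) < tol &&
    a@nrows == b@nrows && a@ncols == b@ncols
}

# cells where every layer is non-NA
jointValidMask <- function(stack) {
  ok <- !is.na(stack@layers[[1]])
  for (m in stack@layers[-1]) ok <- ok & !is.na(m)
  ok
}

## ---- I/O: ESRI ASCII grid --------------------------------------------------

#' Read a raster layer from an ESRI ASCII grid file
#'
#' Reads the plain-text `.asc` format (header of `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`, then values in
#' row-major order from the north). If a `.prj` sidecar file exists it is
#' checked: projected coordinate systems are rejected, since all package
#' geometry assumes geographic lon/lat degrees.
#'
#' @param path path to the `.asc` file.
#' @param name layer name; defaults to the file name without extension.
#' @return a [RasterLayer-class]
#' @export
readAsciiGrid <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  prj <- sub("\\.asc$", ".prj", path, ignore.case = TRUE)
  if (prj != path && file.exists(prj)) {
    wkt <- paste(readLines(prj, warn = FALSE), collapse = " ")
    if (grepl("PROJCS", wkt, ignore.case = TRUE)) {
      crsName <- sub('.*PROJCS\\[\\"([^\\"]+)\\".*', "\\1", wkt)
      stop("raster is in a projected CRS ('", crsName,
           "'); geographic lon/lat coordinates are required")
    }
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid <- geoGrid(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize,
                  hdr$cellsize, nr, nc)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  rasterLayer(name, grid, m)
}

#' Write a raster layer as an ESRI ASCII grid file
#'
#' Values round-trip through [readAsciiGrid()] to full double precision.
#' A minimal geographic `.prj` sidecar (WGS84) is written alongside.
#'
#' @param layer a [RasterLayer-class]
#' @param path output `.asc` path.
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly
#' @export
writeAsciiGrid <- function(layer, path, nodata = -9999) {
  g <- layer@grid
  m <- layer@values
  if (any(m == nodata, na.rm = TRUE))
    stop("data contain the nodata sentinel ", nodata)
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", g@ncols),
    paste("nrows", g@nrows),
    paste("xllcorner", formatC(g@originLon, digits = 15, format = "g")),
    paste("yllcorner", formatC(g@originLat - g@nrows * g@cellSize,
                               digits = 15, format = "g")),
    paste("cellsize", formatC(g@cellSize, digits = 15, format = "g")),
    paste("nodata_value", nodata)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  prj <- sub("\\.asc$", ".prj", path, ignore.case = TRUE)
  if (prj != path)
    writeLines(paste0('GEOGCS["WGS 84",DATUM["WGS_1984",',
                      'SPHEROID["WGS 84",6378137,298.257223563]],',
                      'PRIMEM["Greenwich",0],UNIT["degree",0.0174532925199433]]'),
               prj)
  invisible(path)
}

#' Read/write a whole stack as a directory of ASCII grids
#' @param dir directory of `.asc` files (read) or target directory (write).
#' @param stack a [RasterStack-class] (write).
#' @return a [RasterStack-class] (read) or `dir` invisibly (write)
#' @export
readStackDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc files in ", dir)
  layers <- lapply(files, readAsciiGrid)
  g <- layers[[1]]@grid
  for (l in layers[-1])
    if (!sameGrid(g, l@grid)) stop("layers in ", dir, " are not pixel-aligned")
  rasterStack(g, layers)
}

#' @rdname readStackDir
#' @export
writeStackDir <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stack@layers))
    writeAsciiGrid(rasterLayer(nm, stack@grid, stack@layers[[nm]]),
                   file.path(dir, paste0(nm, ".asc")))
  invisible(dir)
}

## ---- aggregation, masking, extraction --------------------------------------

#' Aggregate a stack to a coarser resolution by block means
#'
#' Each output cell is the mean of the non-nodata values in the
#' corresponding `factor x factor` block of input cells; blocks that are
#' all nodata become nodata. The output cell size is `factor` times the
#' input cell size. Trailing rows/columns that do not fill a whole block
#' are truncated with a warning.
#'
#' @param stack a [RasterStack-class]
#' @param factor positive integer aggregation factor.
#' @return a [RasterStack-class] on the coarser grid
#' @export
aggregateStack <- function(stack, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(stack)
  g <- stack@grid
  nr <- g@nrows %/% factor
  nc <- g@ncols %/% factor
  if (nr < 1L || nc < 1L) stop("factor larger than the grid")
  if (nr * factor != g@nrows || nc * factor != g@ncols)
    warning("grid not divisible by factor; trailing rows/cols truncated")
  outGrid <- geoGrid(g@originLon, g@originLat, g@cellSize * factor, nr, nc)
  rowIdx <- rep(seq_len(nr), each = factor)
  colIdx <- rep(seq_len(nc), each = factor)
  agg <- function(m) {
    m <- m[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
    cnt <- !is.na(m)
    m0 <- m; m0[is.na(m0)] <- 0
    sums <- rowsum(m0, rowIdx)            # nr x (nc*factor)
    nums <- rowsum(cnt + 0, rowIdx)
    sums <- t(rowsum(t(sums), colIdx))    # nr x nc
    nums <- t(rowsum(t(nums), colIdx))
    out <- sums / nums
    out[nums == 0] <- NA_real_
    dimnames(out) <- NULL
    out
  }
  rasterStack(outGrid, lapply(stack@layers, agg))
}

#' Mask a stack to a calibration area
#'
#' Cells whose centres fall outside the area become nodata; cells inside
#' are unchanged. Works on any grid: membership is re-evaluated from the
#' area's geometry when the stack's grid differs from the area's
#' reference grid.
#'
#' @param stack a [RasterStack-class]
#' @param area a [CalibrationArea-class]
#' @return a [RasterStack-class]
#' @export
maskStack <- function(stack, area) {
  m <- areaMask(area, stack@grid)
  if (!any(m & jointValidMask(stack)))
    stop("area does not overlap grid")
  rasterStack(stack@grid, lapply(stack@layers, function(v) {
    v[!m] <- NA_real_
    v
  }))
}

#' Extract layer values at points
#'
#' Returns the value of the cell containing each point, for every layer.
#' Points outside the grid extent are flagged (`outside = TRUE`), and
#' points landing on cells where any layer is nodata are flagged
#' (`nodata = TRUE`); neither is silently dropped.
#'
#' @param stack a [RasterStack-class]
#' @param points an [OccurrenceSet-class], or a data.frame with `lon` and
#'   `lat` columns.
#' @return data.frame: `id`, `lon`, `lat`, one column per layer,
#'   `outside`, `nodata`
#' @export
extractValues <- function(stack, points) {
  if (methods::is(points, "OccurrenceSet")) points <- points@records
  if (!all(c("lon", "lat") %in% names(points)))
    stop("points need 'lon' and 'lat' columns")
  id <- if ("id" %in% names(points)) points$id else seq_len(nrow(points))
  rc <- cellFromXY(stack@grid, points$lon, points$lat)
  out <- data.frame(id = id, lon = points$lon, lat = points$lat)
  inIdx <- which(!rc$outside)
  lin <- rc$row[inIdx] + (rc$col[inIdx] - 1L) * stack@grid@nrows
  for (nm in names(stack@layers)) {
    v <- rep(NA_real_, nrow(points))
    v[inIdx] <- stack@layers[[nm]][lin]
    out[[nm]] <- v
  }
  out$outside <- rc$outside
  vals <- as.matrix(out[names(stack@layers)])
  out$nodata <- !rc$outside & apply(is.na(vals), 1, any)
  out
}
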
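#' @include geo-core.R
NULL

#' Bioclim-style summaries of monthly solar radiation
#'
#' Collapses 12 monthly solar-radiation layers (January..December order)
#' into six derived layers describing annual averages and extremes:
#'
#' * `AMSR`  — annual mean;
#' * `SRMax` — value of the month with maximum radiation;
#' * `SRMin` — value of the month with minimum radiation;
#' * `RSR`   — range, `SRMax - SRMin`;
#' * `ASRQH` — mean of the 3-consecutive-month quarter with the highest
#'   mean;
#' * `ASRQL` — mean of the quarter with the lowest mean.
#'
#' Quarters are the 12 windows of three consecutive calendar months,
#' including the December-January wrap, following bioclim convention.
#' Window ties are value-identical; the first window in January-start
#' order is the one reported. A cell with any nodata month is nodata in
#' all six outputs.
#'
#' @param monthly a [RasterStack-class] of exactly 12 layers, ordered
#'   Jan..Dec.
#' @return a [RasterStack-class] of the six derived layers
#' @examples
#' g <- geoGrid(0, 2, 1, 2, 2)
#' months <- lapply(1:12, function(m) matrix(m, 2, 2))
#' names(months) <- sprintf("sr%02d", 1:12)
#' out <- bioclimSR(rasterStack(g, months))
#' out@layers$RSR[1, 1]   # 11
#' @export
bioclimSR <- function(monthly) {
  if (nLayers(monthly) != 12L)
    stop("a monthly stack must have exactly 12 layers, got ",
         nLayers(monthly))
  g <- monthly@grid
  n <- g@nrows * g@ncols
  M <- vapply(monthly@layers, as.numeric, numeric(n))   # n x 12
  bad <- apply(is.na(M), 1, any)
  quarters <- vapply(1:12, function(m) {
    idx <- ((m - 1):(m + 1)) %% 12 + 1
    rowMeans(M[, idx, drop = FALSE])
  }, numeric(n))                                         # n x 12 windows
  srMax <- apply(M, 1, max)
  srMin <- apply(M, 1, min)
  out <- list(
    AMSR  = rowMeans(M),
    SRMax = srMax,
    SRMin = srMin,
    RSR   = srMax - srMin,
    ASRQH = apply(quarters, 1, max),
    ASRQL = apply(quarters, 1, min))
  out <- lapply(out, function(v) {
    v[bad] <- NA_real_
    matrix(v, g@nrows, g@ncols)
  })
  rasterStack(g, out)
}
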
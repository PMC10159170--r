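#' @include geo-core.R
NULL

#' Pairwise Pearson correlations over an area
#'
#' Correlation matrix of the stack's layers over all jointly valid cells
#' (cells where every layer has data). Zero-variance layers get `NA`
#' rows/columns and are listed in the `"undefined"` attribute.
#'
#' @param stack a [RasterStack-class], typically masked to a calibration
#'   area.
#' @return correlation matrix with attributes `nCells` and `undefined`
#' @export
corrMatrix <- function(stack) {
  if (nLayers(stack) < 2) stop("need at least 2 layers")
  ok <- which(jointValidMask(stack))
  if (length(ok) < 3) stop("need at least 3 jointly valid cells")
  X <- vapply(stack@layers, function(m) m[ok], numeric(length(ok)))
  sds <- apply(X, 2, stats::sd)
  flat <- names(which(sds == 0))
  cm <- suppressWarnings(stats::cor(X))
  cm[flat, ] <- NA_real_
  cm[, flat] <- NA_real_
  diag(cm) <- 1
  attr(cm, "nCells") <- length(ok)
  attr(cm, "undefined") <- flat
  cm
}

#' Maximal groups of mutually weakly correlated variables
#'
#' All maximal variable sets in which every pair satisfies
#' `|r| <= threshold` — the maximal cliques of the compatibility graph —
#' sorted by decreasing size. Variables with undefined correlations are
#' excluded.
#'
#' @param cm correlation matrix (as from [corrMatrix()]).
#' @param threshold pairwise correlation cutoff (default 0.8).
#' @return list of character vectors (each sorted), largest first
#' @export
lowCorrGroups <- function(cm, threshold = 0.8) {
  vars <- rownames(cm)
  drop <- vars[apply(is.na(cm) & col(cm) != row(cm), 1, any)]
  vars <- setdiff(vars, drop)
  if (!length(vars)) return(list())
  a <- abs(cm[vars, vars, drop = FALSE]) <= threshold
  diag(a) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  cl <- igraph::max_cliques(g)
  groups <- lapply(cl, function(x) sort(vars[as.integer(x)]))
  groups[order(-lengths(groups),
               vapply(groups, paste, character(1), collapse = ","))]
}

#' Diagnose range truncation of occurrence environments
#'
#' Compares the distribution of each variable at occurrences with its
#' distribution across the calibration area. A variable is flagged
#' `truncated_low` when the occurrences' 2.5th percentile falls at or
#' below the area's `tail` quantile (the occurrences reach the bottom of
#' what the area offers, so the lower niche limit cannot be
#' characterized), and symmetrically `truncated_high`. Shared-bin
#' histogram tables for plotting are attached.
#'
#' @param occValues data.frame of variable values at occurrences (e.g.
#'   from [extractValues()]).
#' @param areaValues data.frame of variable values across the area (e.g.
#'   a background sample or all valid cells).
#' @param vars variables to diagnose; default the columns common to both
#'   tables, excluding bookkeeping columns.
#' @param tail area tail quantile (default 0.025).
#' @param nBins histogram bin count.
#' @return data.frame with occurrence/area ranges, central 95% interval
#'   and truncation flags; histogram tables in attribute `"histograms"`
#' @export
rangeTruncation <- function(occValues, areaValues, vars = NULL,
                            tail = 0.025, nBins = 20L) {
  skip <- c("id", "cell", "lon", "lat", "outside", "nodata")
  if (is.null(vars))
    vars <- setdiff(intersect(names(occValues), names(areaValues)), skip)
  hists <- list()
  rows <- lapply(vars, function(v) {
    xo <- occValues[[v]]; xa <- areaValues[[v]]
    xo <- xo[!is.na(xo)]; xa <- xa[!is.na(xa)]
    if (length(xo) < 20)
      stop("need >= 20 occurrence values for ", v)
    if (stats::sd(xa) == 0 || stats::sd(xo) == 0)
      return(data.frame(variable = v, occ_min = NA, occ_q025 = NA,
                        occ_q975 = NA, occ_max = NA, area_min = NA,
                        area_max = NA, truncated_low = NA,
                        truncated_high = NA, defined = FALSE))
    qo <- stats::quantile(xo, c(0.025, 0.975), names = FALSE)
    qa <- stats::quantile(xa, c(tail, 1 - tail), names = FALSE)
    edges <- seq(min(xa, xo), max(xa, xo), length.out = nBins + 1L)
    hists[[v]] <<- data.frame(
      lower = edges[-length(edges)], upper = edges[-1],
      occ = graphics::hist(xo, breaks = edges, plot = FALSE)$counts,
      area = graphics::hist(xa, breaks = edges, plot = FALSE)$counts)
    data.frame(variable = v, occ_min = min(xo), occ_q025 = qo[1],
               occ_q975 = qo[2], occ_max = max(xo), area_min = min(xa),
               area_max = max(xa),
               truncated_low = qo[1] <= qa[1],
               truncated_high = qo[2] >= qa[2],
               defined = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "histograms") <- hists
  out
}

#' Assemble the initial variable pool
#'
#' Ranks variables by (1) position in the user's priority list (variables
#' judged biologically relevant come first; this judgment is never
#' automated), (2) fewer truncation flags, (3) lower mean absolute
#' correlation; then selects, among the maximal weakly-correlated groups
#' that contain all `keep` variables, the largest one (ties broken by
#' better summed rank). The pool is returned in rank order. Intended to
#' be computed once, on a designated reference area, and reused across
#' all calibration areas.
#'
#' @param groups list of variable groups from [lowCorrGroups()].
#' @param diagnosis truncation table from [rangeTruncation()], or `NULL`.
#' @param cm the correlation matrix (for the mean-|r| tie-break), or
#'   `NULL`.
#' @param keep character vector of variables that must be in the pool, in
#'   priority order.
#' @param maxSize optional cap on pool size; the top-ranked `maxSize`
#'   pool members are kept (any subset of a compatible group is itself
#'   compatible).
#' @return character vector: the variable pool, ranked
#' @export
initialPool <- function(groups, diagnosis = NULL, cm = NULL,
                        keep = character(0), maxSize = Inf) {
  vars <- sort(unique(unlist(groups)))
  if (!length(vars)) stop("no variable groups supplied")
  bad <- setdiff(keep, vars)
  if (length(bad))
    stop("keep variables not available: ", paste(bad, collapse = ", "))
  flags <- stats::setNames(rep(0, length(vars)), vars)
  if (!is.null(diagnosis)) {
    d <- diagnosis[diagnosis$variable %in% vars & diagnosis$defined, ]
    flags[d$variable] <- (d$truncated_low + d$truncated_high)
  }
  meanR <- stats::setNames(rep(0, length(vars)), vars)
  if (!is.null(cm)) {
    sub <- abs(cm[vars, vars, drop = FALSE])
    diag(sub) <- NA
    meanR[vars] <- rowMeans(sub, na.rm = TRUE)
  }
  prio <- stats::setNames(rep(length(keep) + 1L, length(vars)), vars)
  prio[keep] <- seq_along(keep)
  rank <- order(prio[vars], flags[vars], meanR[vars], vars)
  ranked <- vars[rank]
  hasKeep <- vapply(groups, function(grp) all(keep %in% grp), logical(1))
  if (length(keep) && !any(hasKeep)) {
    pair <- "no single incompatible pair identified"
    if (!is.null(cm) && length(keep) > 1) {
      sub <- abs(cm[keep, keep, drop = FALSE])
      sub[lower.tri(sub, diag = TRUE)] <- -Inf
      idx <- which(sub == max(sub), arr.ind = TRUE)[1, , drop = FALSE]
      pair <- paste0(keep[idx[1]], " vs ", keep[idx[2]],
                     " (|r| = ", round(sub[idx], 3), ")")
    }
    stop("keep list is internally incompatible: ", pair)
  }
  cand <- if (length(keep)) groups[hasKeep] else groups
  scores <- vapply(cand, function(grp)
    sum(match(grp, ranked)), numeric(1))
  best <- cand[[order(-lengths(cand), scores)[1]]]
  pool <- ranked[ranked %in% best]
  utils::head(pool, maxSize)
}
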
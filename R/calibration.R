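#' @include models.R
NULL

#' Enumerate candidate model specifications
#'
#' All variable subsets of size >= `minSize` from the pool, crossed with
#' the five response types and — for the Maxent-style algorithm — the six
#' regularization multipliers. For a pool of `V` variables this yields
#' `(2^V - V - 1) * 5` GLM candidates and `(2^V - V - 1) * 30` Maxent
#' candidates at the default `minSize = 2`. Order is deterministic:
#' subsets in lexicographic index order (smaller subsets first within
#' equal leading indices as produced by combination order), then response
#' type, then multiplier.
#'
#' @param pool character vector of pool variables (pool order matters).
#' @param algorithm `"glm"` or `"maxent"`.
#' @param minSize minimum subset size (default 2).
#' @param rms regularization multipliers for maxent.
#' @param rtypes response types.
#' @return data.frame: `subset` (comma-separated variables), `size`,
#'   `rtype`, `rm` (`NA` for glm)
#' @export
enumerateCandidates <- function(pool, algorithm = c("glm", "maxent"),
                                minSize = 2L, rms = rmDefaults,
                                rtypes = responseTypes) {
  algorithm <- match.arg(algorithm)
  V <- length(pool)
  if (V < minSize) stop("pool smaller than the minimum subset size")
  subsets <- unlist(lapply(minSize:V, function(k)
    utils::combn(pool, k, simplify = FALSE)), recursive = FALSE)
  subs <- vapply(subsets, paste, character(1), collapse = ",")
  sizes <- lengths(subsets)
  if (algorithm == "glm") {
    out <- expand.grid(rtype = rtypes, subset = subs,
                       stringsAsFactors = FALSE)[, c("subset", "rtype")]
    out$rm <- NA_real_
  } else {
    out <- expand.grid(rm = rms, rtype = rtypes, subset = subs,
                       stringsAsFactors = FALSE)[, c("subset", "rtype", "rm")]
  }
  out$size <- sizes[match(out$subset, subs)]
  rownames(out) <- NULL
  out[c("subset", "size", "rtype", "rm")]
}

#' Split occurrences into training and testing halves
#'
#' Seeded random partition; train and test are disjoint and their union
#' is the input. `fraction = 1` returns an empty test set (training-only
#' evaluation, flagged downstream).
#'
#' @param occ an [OccurrenceSet-class].
#' @param fraction training fraction (default 0.5).
#' @param seed integer seed.
#' @return list with `train` and `test` [OccurrenceSet-class] objects
#' @export
splitOccurrences <- function(occ, fraction = 0.5, seed = 1L) {
  n <- nOcc(occ)
  set.seed(seed)
  nTrain <- round(fraction * n)
  idx <- sort(sample.int(n, nTrain))
  r <- occ@records
  list(train = occurrenceSet(r[idx, , drop = FALSE]),
       test = occurrenceSet(r[setdiff(seq_len(n), idx), , drop = FALSE]))
}

#' Omission rate at an E% training threshold
#'
#' The threshold is the `E` quantile (linear-interpolation empirical
#' quantile) of predicted suitability at training presences — the value
#' admitting an `E` fraction of training omission. The omission rate is
#' the fraction of testing presences predicted strictly below it.
#'
#' @param trainPred predictions at training presences.
#' @param testPred predictions at testing presences.
#' @param E acceptable omission error (default 0.05).
#' @return list with `threshold` and `rate`
#' @export
omissionRate <- function(trainPred, testPred, E = 0.05) {
  thr <- stats::quantile(trainPred, E, names = FALSE, type = 7)
  list(threshold = thr,
       rate = if (length(testPred)) mean(testPred < thr) else NA_real_)
}

#' Partial ROC test of model significance
#'
#' AUC-ratio construction: the ROC curve of suitability at testing
#' presences versus the proportion of the background predicted present
#' is restricted to the region with omission at most `E` (sensitivity >=
#' 1 - E); the partial AUC of the model curve is divided by the partial
#' area under the random-prediction diagonal over the same region. For
#' each bootstrap iteration a fraction of the testing presences is
#' resampled with replacement; the p-value is the fraction of iterations
#' with AUC ratio <= 1. Constant (degenerate) predictions are flagged and
#' given `p = 1`.
#'
#' The omission-constrained threshold region is fixed once, from the
#' full testing set, and only the sensitivity curve is bootstrapped.
#' Re-selecting the region inside each bootstrap sample conditions the
#' kept sensitivities on exceeding `1 - E` and biases the AUC ratio
#' upward, making truly random predictions appear significant; with the
#' region fixed, the test is calibrated (about 5% false significance on
#' random models) while retaining its power on informative ones.
#'
#' @param testPred predictions at testing presences (>= 10 recommended).
#' @param bgPred predictions at background points.
#' @param E maximum acceptable omission (default 0.05).
#' @param iterations bootstrap iterations (default 500).
#' @param bootFraction fraction of presences resampled per iteration.
#' @param seed integer seed.
#' @param nBins threshold discretization used for speed.
#' @return list with `meanRatio`, `p`, `ratios`, `degenerate`
#' @export
partialROC <- function(testPred, bgPred, E = 0.05, iterations = 500L,
                       bootFraction = 0.5, seed = 1L, nBins = 200L) {
  rng <- range(c(testPred, bgPred))
  if (diff(rng) == 0 || stats::sd(bgPred) == 0)
    return(list(meanRatio = NA_real_, p = 1, ratios = numeric(0),
                degenerate = TRUE))
  edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  # proportion of background at or above each threshold (bin lower edge)
  bgBin <- findInterval(bgPred, edges, rightmost.closed = TRUE)
  bgTab <- tabulate(bgBin, nBins)
  propArea <- rev(cumsum(rev(bgTab))) / length(bgPred)
  presBin <- findInterval(testPred, edges, rightmost.closed = TRUE)
  n <- length(testPred)
  m <- max(1L, ceiling(bootFraction * n))
  # kept region: sens and propArea are both non-increasing in the bin
  # index, so "omission <= E" is the prefix of bins with full-test-set
  # sensitivity >= 1 - E (fixed across iterations; see Details)
  sensFull <- rev(cumsum(rev(tabulate(presBin, nBins)))) / n
  K <- sum(sensFull >= 1 - E)
  if (K < 2)
    return(list(meanRatio = NA_real_, p = 1, ratios = numeric(0),
                degenerate = TRUE))
  x <- propArea[K:1]
  dx <- diff(x)
  pRand <- sum(dx * (x[-1] + x[-K]) / 2)
  if (pRand <= 0)
    return(list(meanRatio = NA_real_, p = 1, ratios = numeric(0),
                degenerate = TRUE))
  set.seed(seed)
  draws <- matrix(presBin[sample.int(n, m * iterations, replace = TRUE)],
                  nrow = m)
  ratios <- vapply(seq_len(iterations), function(it) {
    sens <- rev(cumsum(rev(tabulate(draws[, it], nBins)))) / m
    yv <- sens[K:1]
    pAuc <- sum(dx * (yv[-1] + yv[-K]) / 2)
    pAuc / pRand
  }, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios))
    return(list(meanRatio = NA_real_, p = 1, ratios = numeric(0),
                degenerate = TRUE))
  list(meanRatio = mean(ratios), p = mean(ratios <= 1), ratios = ratios,
       degenerate = FALSE)
}

#' Small-sample corrected AIC from counts
#'
#' `AICc = 2k - 2 lnL + 2k(k + 1) / (n - k - 1)`; undefined (with a
#' warning-free `NA`) when `n <= k + 1`.
#'
#' @param k parameter count.
#' @param n sample size.
#' @param logLik log-likelihood.
#' @return numeric
#' @examples
#' aicc(3, 20, -100)  # 207.5
#' @export
aicc <- function(k, n, logLik) {
  if (n <= k + 1) return(NA_real_)
  2 * k - 2 * logLik + 2 * k * (k + 1) / (n - k - 1)
}

#' Warren-Seifert AICc of a Maxent-style model
#'
#' The raw prediction is renormalized to sum to 1 over the valid cells of
#' the calibration extent; the log-likelihood is the sum of log
#' normalized raw scores at the occurrence cells; `k` is the number of
#' non-zero penalized coefficients. Undefined when the occurrence count
#' does not exceed `k + 1` (candidate flagged non-comparable).
#'
#' @param model a maxent [EnmModel-class].
#' @param stack the calibration-extent [RasterStack-class] (masked to the
#'   calibration area).
#' @param occ an [OccurrenceSet-class] (all occurrences used for
#'   calibration).
#' @return list with `aicc`, `logLik`, `k`, `n`
#' @export
aiccWarren <- function(model, stack, occ) {
  if (model@algorithm != "maxent")
    stop("Warren-Seifert AICc is defined for maxent models")
  raw <- predictEnm(model, stack, type = "raw")
  v <- raw@values
  tot <- sum(v, na.rm = TRUE)
  rc <- cellFromXY(stack@grid, occ@records$lon, occ@records$lat)
  ok <- !rc$outside
  cellRaw <- rep(NA_real_, nOcc(occ))
  cellRaw[ok] <- v[cbind(rc$row[ok], rc$col[ok])]
  usable <- !is.na(cellRaw)
  if (!all(usable))
    warning(sum(!usable), " occurrence(s) outside the calibration extent",
            " ignored in AICc")
  n <- sum(usable)
  ll <- sum(log(pmax(cellRaw[usable] / tot, 1e-300)))
  list(aicc = aicc(model@k, n, ll), logLik = ll, k = model@k, n = n)
}

#' Apply the three-criterion model selection rule
#'
#' Keeps candidates that are statistically significant (partial ROC
#' `p <= pMax`) and accurate (omission `<= omMax`); among those, delta
#' AIC(c) is computed from the minimum within the survivors and
#' candidates with delta `<= deltaMax` are selected. When no candidate
#' passes both screens, selection falls back to delta AIC(c) among the
#' significant-only candidates, with a warning. Candidates whose fit
#' failed (non-empty `flag`) or whose criteria are undefined are never
#' selected.
#'
#' @param results data.frame with columns `proc_p`, `omission`, `aic`,
#'   `flag` (and any identifying columns, carried through).
#' @param pMax,omMax,deltaMax the three cutoffs (defaults 0.05, 0.05, 2).
#' @return the input with `delta_aic` and `selected` columns added
#' @export
selectModels <- function(results, pMax = 0.05, omMax = 0.05, deltaMax = 2) {
  if (!nrow(results)) stop("no evaluable results")
  usable <- !nzchar(results$flag) & !is.na(results$aic)
  if (!any(usable)) stop("all candidates failed fitting or evaluation")
  sig <- usable & !is.na(results$proc_p) & results$proc_p <= pMax
  acc <- sig & !is.na(results$omission) & results$omission <= omMax
  pool <- if (any(acc)) acc else {
    warning("no candidate met both significance and omission screens; ",
            "falling back to delta AIC(c) among significant models")
    sig
  }
  results$delta_aic <- NA_real_
  results$selected <- FALSE
  if (any(pool)) {
    best <- min(results$aic[pool])
    results$delta_aic[pool] <- results$aic[pool] - best
    results$selected[pool] <- results$delta_aic[pool] <= deltaMax
  }
  results
}

#' Run one treatment: enumerate, fit, evaluate, select, refit
#'
#' The full calibration loop for one resolution x calibration-area x
#' algorithm combination: draw the shared background sample, split the
#' occurrences, fit every candidate on the training half, evaluate each
#' by partial ROC, omission rate and AIC (glm) or Warren-Seifert AICc
#' (maxent), apply [selectModels()], and refit the winning specification
#' (lowest AIC among the selected) on all occurrences.
#'
#' @param pool variable pool (character).
#' @param algorithm `"glm"` or `"maxent"`.
#' @param occ an [OccurrenceSet-class] (cleaned/thinned).
#' @param area a [CalibrationArea-class].
#' @param stack the resolution's [RasterStack-class] (unmasked).
#' @param label treatment label used in reporting.
#' @param bgN background sample size (default 20000).
#' @param E omission error (default 0.05).
#' @param splitFraction training fraction.
#' @param procIterations,procBootFraction partial ROC settings.
#' @param pMax,omMax,deltaMax selection cutoffs.
#' @param rms regularization multipliers (maxent).
#' @param rtypes response types.
#' @param seed integer seed (background, split, bootstrap).
#' @return list of class `TreatmentResult`: `label`, `results`
#'   (per-candidate data.frame), `winner` (spec row or `NULL`),
#'   `winnerVariables`, `final` ([EnmModel-class] refit on all
#'   occurrences), `threshold` (E-threshold of the final model), `bg`
#' @export
runTreatment <- function(pool, algorithm, occ, area, stack,
                         label = paste0(area@name, "_", algorithm),
                         bgN = 20000L, E = 0.05, splitFraction = 0.5,
                         procIterations = 500L, procBootFraction = 0.5,
                         pMax = 0.05, omMax = 0.05, deltaMax = 2,
                         rms = rmDefaults, rtypes = responseTypes,
                         seed = 1L) {
  masked <- maskStack(stack, area)
  bg <- suppressWarnings(sampleBackground(area, stack, bgN, seed = seed))
  occVals <- extractValues(masked, occ)
  inside <- !occVals$outside & !occVals$nodata
  if (!all(inside))
    warning(sum(!inside), " occurrence(s) outside area '", area@name,
            "' excluded from treatment ", label)
  occIn <- occurrenceSet(occ@records[inside, , drop = FALSE])
  occVals <- occVals[inside, , drop = FALSE]
  sp <- splitOccurrences(occIn, splitFraction, seed = seed + 1L)
  trainIds <- sp$train@records$id
  isTrain <- occVals$id %in% trainIds
  trainVals <- occVals[isTrain, , drop = FALSE]
  testVals <- occVals[!isTrain, , drop = FALSE]
  cands <- enumerateCandidates(pool, algorithm, rms = rms, rtypes = rtypes)
  # extent cells for AICc renormalization (maxent)
  evalRows <- vector("list", nrow(cands))
  models <- vector("list", nrow(cands))
  for (ci in seq_len(nrow(cands))) {
    vars <- strsplit(cands$subset[ci], ",")[[1]]
    rtype <- cands$rtype[ci]
    model <- tryCatch(
      if (algorithm == "glm")
        fitGLM(trainVals, bg, vars, rtype)
      else
        fitMaxent(trainVals, bg, vars, rtype, rm = cands$rm[ci]),
      error = function(e)
        new("EnmModel", algorithm = algorithm, variables = vars,
            responseType = rtype,
            rm = if (algorithm == "maxent") cands$rm[ci] else NA_real_,
            center = stats::setNames(numeric(length(vars)), vars),
            scale = stats::setNames(rep(1, length(vars)), vars),
            coef = c(`(Intercept)` = 0), logLik = NA_real_,
            entropy = NA_real_, logZ = NA_real_, k = 0, converged = FALSE,
            flag = paste("failed:", conditionMessage(e))))
    models[[ci]] <- model
    row <- cands[ci, , drop = FALSE]
    row$flag <- model@flag
    row$proc_ratio <- NA_real_; row$proc_p <- NA_real_
    row$omission <- NA_real_; row$threshold <- NA_real_
    row$aic <- NA_real_; row$k <- model@k
    if (!nzchar(model@flag) ||
        startsWith(model@flag, "unstable")) {
      ptype <- if (algorithm == "maxent") "cloglog" else "prob"
      trainPred <- predictEnm(model, trainVals, type = ptype)
      testPred <- predictEnm(model, testVals, type = ptype)
      bgPred <- predictEnm(model, bg, type = ptype)
      om <- omissionRate(trainPred, testPred, E)
      row$omission <- om$rate; row$threshold <- om$threshold
      pr <- partialROC(testPred, bgPred, E, iterations = procIterations,
                       bootFraction = procBootFraction, seed = seed + 2L)
      row$proc_ratio <- pr$meanRatio; row$proc_p <- pr$p
      row$aic <- if (algorithm == "glm") {
        2 * model@k - 2 * model@logLik
      } else {
        aiccWarren(model, masked, occIn)$aicc
      }
      if (is.na(row$aic) && !nzchar(row$flag))
        row$flag <- "failed: AICc undefined (n <= k + 1)"
    }
    evalRows[[ci]] <- row
  }
  results <- do.call(rbind, evalRows)
  rownames(results) <- NULL
  results <- selectModels(results, pMax, omMax, deltaMax)
  winner <- NULL; final <- NULL; winnerVars <- character(0); thr <- NA_real_
  if (any(results$selected)) {
    sel <- which(results$selected)
    winner <- results[sel[which.min(results$aic[sel])], , drop = FALSE]
    winnerVars <- strsplit(winner$subset, ",")[[1]]
    final <- if (algorithm == "glm")
      fitGLM(occVals, bg, winnerVars, winner$rtype)
    else
      fitMaxent(occVals, bg, winnerVars, winner$rtype, rm = winner$rm)
    ptype <- if (algorithm == "maxent") "cloglog" else "prob"
    thr <- stats::quantile(predictEnm(final, occVals, type = ptype), E,
                           names = FALSE)
  }
  structure(list(label = label, algorithm = algorithm, area = area@name,
                 pool = pool, results = results, winner = winner,
                 winnerVariables = winnerVars, final = final,
                 threshold = thr, bg = bg, nTrain = nrow(trainVals),
                 nTest = nrow(testVals)),
            class = "TreatmentResult")
}
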
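#' @include calibration.R
NULL

#' Jackknife variable importance for a Maxent-style model
#'
#' For each variable of the winning specification, the model is refitted
#' with only that variable and with all variables but it. The metric is
#' the training gain: the mean log normalized raw score at training
#' presences, relative to a uniform distribution (`mean(log raw) +
#' log N`, 0 for an uninformative model). Contribution shares are the
#' normalized drops in gain when each variable is excluded. Permutation
#' importance is the mean drop in training AUC (presences against the
#' background) over seeded shuffles of the variable's values across all
#' training rows — AUC rather than gain, because the mean linear score
#' of additive (l/q) features is invariant under within-column
#' permutation.
#'
#' @param model the fitted maxent [EnmModel-class] (winning spec).
#' @param presValues,bgValues training tables of base variable values.
#' @param nShuffles permutation-importance shuffles (default 10).
#' @param seed integer seed.
#' @return data.frame: `variable`, `gain_only`, `gain_without`,
#'   `contribution`, `permutation_importance`; attribute `gain_full`
#' @export
jackknifeImportance <- function(model, presValues, bgValues,
                                nShuffles = 10L, seed = 1L) {
  if (model@algorithm != "maxent")
    stop("jackknife importance applies to maxent models")
  vars <- model@variables
  if (length(vars) < 2) stop("need a model with >= 2 variables")
  np <- nrow(presValues)
  gainOf <- function(m, pv) {
    raw <- predictEnm(m, pv, type = "raw")
    n <- np + nrow(bgValues)
    mean(log(pmax(raw, 1e-300))) + log(n)
  }
  refit <- function(vs) {
    rt <- model@responseType
    if (length(vs) == 1 && grepl("p", rt)) {
      # product features need >= 2 variables; drop the p component
      rt <- sub("p", "", rt)
      if (!nzchar(rt)) rt <- "l"
    }
    tryCatch(fitMaxent(presValues, bgValues, vs, rt, rm = model@rm),
             error = function(e) NULL)
  }
  full <- gainOf(model, presValues)
  allRows <- rbind(as.data.frame(presValues)[vars],
                   as.data.frame(bgValues)[vars])
  isPres <- c(rep(TRUE, np), rep(FALSE, nrow(bgValues)))
  trainAUC <- function(tab) {
    s <- predictEnm(model, tab, type = "raw")
    r <- rank(s)
    (sum(r[isPres]) - np * (np + 1) / 2) / (np * sum(!isPres))
  }
  aucFull <- trainAUC(allRows)
  set.seed(seed)
  rows <- lapply(vars, function(v) {
    mOnly <- refit(v)
    mWithout <- refit(setdiff(vars, v))
    permDrop <- mean(vapply(seq_len(nShuffles), function(s) {
      shuf <- allRows
      shuf[[v]] <- sample(shuf[[v]])
      aucFull - trainAUC(shuf)
    }, numeric(1)))
    data.frame(variable = v,
               gain_only = if (is.null(mOnly)) NA_real_
                           else gainOf(mOnly, presValues),
               gain_without = if (is.null(mWithout)) NA_real_
                              else gainOf(mWithout, presValues),
               permutation_importance = permDrop)
  })
  out <- do.call(rbind, rows)
  drop <- pmax(full - out$gain_without, 0)
  out$contribution <- if (all(is.na(drop)) || sum(drop, na.rm = TRUE) == 0)
    rep(1 / nrow(out), nrow(out)) else drop / sum(drop, na.rm = TRUE)
  out <- out[c("variable", "gain_only", "gain_without", "contribution",
               "permutation_importance")]
  attr(out, "gain_full") <- full
  attr(out, "auc_full") <- aucFull
  out
}

#' Sequential deviance decomposition of a weighted GLM
#'
#' Refits the winning weighted logistic model with [stats::glm()] and
#' returns the Type I (sequential) analysis of deviance in feature-entry
#' order (linear, then quadratic, then product terms), each tested
#' against a chi-square distribution on its degrees of freedom. The
#' component deviances sum to the null-minus-residual deviance.
#'
#' @param model a glm [EnmModel-class] (for the spec: variables, response
#'   type, weights are reused).
#' @param presValues,bgValues training tables of base variable values.
#' @param wPresence,wAbsence observation weights.
#' @return data.frame: `term`, `df`, `deviance`, `resid_df`,
#'   `resid_deviance`, `p`
#' @export
devianceTable <- function(model, presValues, bgValues,
                          wPresence = 1, wAbsence = 10000) {
  if (model@algorithm != "glm")
    stop("deviance decomposition applies to glm models")
  np <- nrow(presValues)
  base <- rbind(as.data.frame(presValues)[model@variables],
                as.data.frame(bgValues)[model@variables])
  F <- buildFeatures(base, model@variables, model@responseType,
                     center = model@center, scale = model@scale)
  dat <- as.data.frame(F)
  names(dat) <- paste0("f", seq_len(ncol(F)))
  dat$y <- c(rep(1, np), rep(0, nrow(bgValues)))
  dat$w <- c(rep(wPresence, np), rep(wAbsence, nrow(bgValues)))
  fml <- stats::as.formula(paste("y ~", paste(names(dat)[seq_len(ncol(F))],
                                              collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = dat, weights = w))
  an <- stats::anova(fit, test = "Chisq")
  out <- data.frame(term = c("NULL", colnames(F)),
                    df = an$Df, deviance = an$Deviance,
                    resid_df = an$`Resid. Df`,
                    resid_deviance = an$`Resid. Dev`,
                    p = an$`Pr(>Chi)`)
  rownames(out) <- NULL
  out
}

#' Project final models over the union of calibration areas
#'
#' Every treatment's final model is transferred (free extrapolation)
#' across the union of the four calibration areas at its own resolution:
#' maxent models as cloglog suitability, GLMs as logistic probability
#' rescaled 0-1 over the projection extent. A per-pixel across-treatment
#' standard-deviation layer summarizes how much the transfers disagree.
#'
#' @param treatments list of `TreatmentResult` objects sharing one
#'   resolution.
#' @param areas list of the four [CalibrationArea-class] objects.
#' @param stack the resolution's [RasterStack-class].
#' @return list: `projections` ([RasterStack-class], one layer per
#'   treatment), `variability` ([RasterLayer-class])
#' @export
projectAll <- function(treatments, areas, stack) {
  g <- stack@grid
  union <- matrix(FALSE, g@nrows, g@ncols)
  for (a in areas) union <- union | areaMask(a, g)
  unionStack <- rasterStack(g, lapply(stack@layers, function(v) {
    v[!union] <- NA_real_
    v
  }))
  done <- Filter(function(t) !is.null(t$final), treatments)
  if (!length(done)) stop("no completed treatments to project")
  layers <- lapply(done, function(t) {
    type <- if (t$algorithm == "maxent") "cloglog" else "scaled01"
    predictEnm(t$final, unionStack, type = type)@values
  })
  names(layers) <- vapply(done, `[[`, character(1), "label")
  A <- simplify2array(layers)            # nr x nc x k
  sdv <- apply(A, c(1, 2), function(x)
    if (all(is.na(x))) NA_real_ else stats::sd(x))
  if (length(done) == 1) sdv[!is.na(sdv)] <- 0
  list(projections = rasterStack(g, layers),
       variability = rasterLayer("variability_sd", g, sdv))
}

#' Export predictions into environmental space
#'
#' One row per valid cell of the prediction: the values of three chosen
#' environmental axes, the suitability, and a flag marking cells above
#' the E% training-omission threshold. This table backs 3-D
#' suitability-in-environment-space visualizations.
#'
#' @param prediction a suitability [RasterLayer-class].
#' @param stack the environment [RasterStack-class] (same grid).
#' @param axes three variable names.
#' @param threshold suitability threshold (e.g. the treatment's
#'   `$threshold`).
#' @return data.frame: `cell`, the three axes, `suitability`, `above`
#' @export
envSpaceExport <- function(prediction, stack, axes, threshold) {
  if (length(axes) != 3) stop("exactly three axis variables expected")
  miss <- setdiff(axes, names(stack@layers))
  if (length(miss)) stop("axis variable(s) missing from stack: ",
                         paste(miss, collapse = ", "))
  ok <- which(!is.na(prediction@values) &
                jointValidMask(rasterStack(stack@grid,
                                           stack@layers[axes])))
  out <- data.frame(cell = ok)
  for (a in axes) out[[a]] <- stack@layers[[a]][ok]
  out$suitability <- prediction@values[ok]
  out$above <- out$suitability >= threshold
  out
}

#' Cross-treatment variable-consistency matrix
#'
#' Boolean membership of every pool variable in each treatment's winning
#' set, with per-variable selection frequencies. Failed treatments (no
#' winner) appear as `NA` columns and are excluded from the frequency
#' denominator. Variables selected consistently across treatments are
#' the pipeline's headline output.
#'
#' @param winners named list: treatment label -> character vector of
#'   winning variables, or `NULL`/`NA` for a failed treatment.
#' @param variables the variable universe (e.g. union of pools); default
#'   the union of all winning sets.
#' @return list of class `ConsistencyMatrix`: `matrix` (variables x
#'   treatments, logical), `frequency` (named numeric), `nTreatments`
#' @export
consistencyMatrix <- function(winners, variables = NULL) {
  if (!length(winners)) stop("no treatments supplied")
  ok <- !vapply(winners, function(w) is.null(w) || all(is.na(w)), logical(1))
  if (is.null(variables))
    variables <- sort(unique(unlist(winners[ok])))
  m <- matrix(NA, length(variables), length(winners),
              dimnames = list(variables, names(winners)))
  for (j in which(ok)) m[, j] <- variables %in% winners[[j]]
  freq <- if (any(ok)) rowMeans(m[, ok, drop = FALSE]) else
    stats::setNames(rep(NA_real_, length(variables)), variables)
  structure(list(matrix = m, frequency = freq, nTreatments = sum(ok)),
            class = "ConsistencyMatrix")
}

#' @export
print.ConsistencyMatrix <- function(x, ...) {
  cat("ConsistencyMatrix:", nrow(x$matrix), "variables x",
      ncol(x$matrix), "treatments (", x$nTreatments, "completed )\n")
  print(round(x$frequency, 3))
  invisible(x)
}
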
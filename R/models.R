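#' @include AllClasses.R geo-core.R
NULL

responseTypes <- c("lq", "lp", "q", "qp", "lqp")
rmDefaults <- c(0.1, 0.3, 0.6, 1.0, 2.5, 5.0)

# feature class of each column for a response type and variable set:
# l = the variable itself, q = its square, p = pairwise products of
# distinct variables. Order is deterministic: l block, then q, then p
# (variables in pool order; products in lexicographic index order).
featurePlan <- function(vars, rtype) {
  letters <- strsplit(rtype, "")[[1]]
  if (!length(letters) || anyDuplicated(letters) ||
      !all(letters %in% c("l", "q", "p")))
    stop("unknown response type: ", rtype)
  plan <- list(name = character(0), class = character(0),
               i = integer(0), j = integer(0))
  addF <- function(name, class, i, j = NA_integer_) {
    plan$name <<- c(plan$name, name)
    plan$class <<- c(plan$class, class)
    plan$i <<- c(plan$i, i)
    plan$j <<- c(plan$j, j)
  }
  if ("l" %in% letters)
    for (i in seq_along(vars)) addF(vars[i], "l", i)
  if ("q" %in% letters)
    for (i in seq_along(vars)) addF(paste0("I(", vars[i], "^2)"), "q", i)
  if ("p" %in% letters && length(vars) >= 2)
    for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars))
      addF(paste0(vars[i], ":", vars[j]), "p", i, j)
  plan
}

#' Build the standardized feature matrix for a response type
#'
#' Base variables are z-scored (by the supplied or the table's own
#' means/sds), then expanded per the response-type rule: `l` columns are
#' the variables, `q` their squares, `p` all pairwise products of
#' distinct variables — squares and products computed after
#' standardization.
#'
#' @param values data.frame or matrix of base variable columns.
#' @param vars variable names to use, in pool order.
#' @param rtype response type: one of `lq`, `lp`, `q`, `qp`, `lqp`.
#' @param center,scale optional training means/sds; computed from
#'   `values` when omitted.
#' @return numeric feature matrix with attributes `center`, `scale`
#' @export
buildFeatures <- function(values, vars, rtype, center = NULL, scale = NULL) {
  X <- if (is.matrix(values)) values[, vars, drop = FALSE]
  else as.matrix(as.data.frame(values)[vars])
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2, stats::sd)
  zero <- vars[scale == 0 | is.na(scale)]
  if (length(zero))
    stop("zero-variance variable(s): ", paste(zero, collapse = ", "))
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  plan <- featurePlan(vars, rtype)
  F <- matrix(0, nrow(Z), length(plan$name),
              dimnames = list(NULL, plan$name))
  for (f in seq_along(plan$name)) {
    F[, f] <- switch(plan$class[f],
      l = Z[, plan$i[f]],
      q = Z[, plan$i[f]]^2,
      p = Z[, plan$i[f]] * Z[, plan$j[f]])
  }
  attr(F, "center") <- stats::setNames(center, vars)
  attr(F, "scale") <- stats::setNames(scale, vars)
  attr(F, "class_of") <- stats::setNames(plan$class, plan$name)
  F
}

weightedLogLik <- function(y, w, p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  sum(w * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Fit the weighted logistic presence/pseudo-absence GLM
#'
#' Maximum-likelihood logistic regression contrasting presences (weight
#' `wPresence`) against pseudo-absences (weight `wAbsence`), on the
#' feature expansion of the chosen response type. Returns the weighted
#' log-likelihood and `AIC = 2k - 2 lnL` with `k` counting all estimated
#' coefficients including the intercept. Fits with too few presences,
#' non-convergence, or coefficients diverging towards separation are
#' flagged and excluded from selection downstream.
#'
#' @param presValues,absValues data.frames of base variable values at
#'   presences and pseudo-absences.
#' @param vars variable subset.
#' @param rtype response type.
#' @param wPresence,wAbsence observation weights (defaults 1 and 10000).
#' @return an [EnmModel-class] with attribute-free deterministic predict
#' @export
fitGLM <- function(presValues, absValues, vars, rtype,
                   wPresence = 1, wAbsence = 10000) {
  np <- nrow(presValues)
  base <- rbind(as.matrix(as.data.frame(presValues)[vars]),
                as.matrix(as.data.frame(absValues)[vars]))
  F <- buildFeatures(base, vars, rtype)
  y <- c(rep(1, np), rep(0, nrow(absValues)))
  w <- c(rep(wPresence, np), rep(wAbsence, nrow(absValues)))
  flag <- ""
  if (np < ncol(F) + 5) flag <- "unstable: too few presences for features"
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, F), y, weights = w,
                   family = stats::binomial()))
  beta <- fit$coefficients
  if (anyNA(beta)) {
    flag <- "failed: rank-deficient design"
    beta[is.na(beta)] <- 0
  } else if (!fit$converged) {
    flag <- "failed: IRLS did not converge"
  } else if (max(abs(beta[-1])) > 20 && flag == "") {
    flag <- "failed: apparent separation"
  }
  ll <- weightedLogLik(y, w, fit$fitted.values)
  new("EnmModel", algorithm = "glm", variables = vars,
      responseType = rtype, rm = NA_real_,
      center = attr(F, "center"), scale = attr(F, "scale"),
      coef = beta, logLik = ll, entropy = NA_real_, logZ = NA_real_,
      k = length(beta), converged = fit$converged, flag = flag)
}

# Maxent-convention default per-class regularization, interpolated over
# the presence sample size m (values follow the defaults popularized by
# the reference implementation for linear/quadratic and product features)
betaDefault <- function(class, m) {
  tab <- switch(class,
    l = list(ss = c(10, 30, 100), beta = c(1.00, 0.20, 0.05)),
    q = list(ss = c(0, 10, 17, 30, 100), beta = c(1.30, 0.80, 0.50, 0.25, 0.05)),
    p = list(ss = c(0, 10, 17, 30, 100), beta = c(2.60, 1.60, 0.90, 0.55, 0.05)))
  stats::approx(tab$ss, tab$beta, xout = m, rule = 2)$y
}

# cyclic coordinate descent on the IRLS quadratic approximation of the
# weighted logistic log-likelihood with per-coefficient L1 penalties
# (lambda on the absolute log-likelihood scale); intercept unpenalized
penalizedLogisticCD <- function(X, y, w, lambda, tol = 1e-7,
                                maxOuter = 100L, maxInner = 100L) {
  n <- nrow(X); pdim <- ncol(X)
  beta <- numeric(pdim)
  prev <- mean(w * y) / mean(w)
  b0 <- stats::qlogis(min(max(prev, 1e-12), 1 - 1e-12))
  eta <- rep(b0, n)
  Xb <- as.numeric(X %*% beta)
  converged <- FALSE
  for (outer in seq_len(maxOuter)) {
    mu <- stats::plogis(eta)
    q <- pmax(mu * (1 - mu), 1e-10)
    wq <- w * q
    z <- eta + (y - mu) / q
    resid <- z - eta
    oldB <- c(b0, beta)
    for (inner in seq_len(maxInner)) {
      delta <- 0
      # intercept
      nb0 <- b0 + sum(wq * resid) / sum(wq)
      resid <- resid - (nb0 - b0)
      delta <- max(delta, abs(nb0 - b0)); b0 <- nb0
      for (j in seq_len(pdim)) {
        xj <- X[, j]
        rj <- resid + xj * beta[j]
        num <- sum(wq * xj * rj)
        den <- sum(wq * xj * xj)
        if (den <= 0) next
        nb <- sign(num) * max(0, abs(num) - lambda[j]) / den
        if (nb != beta[j]) {
          resid <- resid - xj * (nb - beta[j])
          delta <- max(delta, abs(nb - beta[j]))
          beta[j] <- nb
        }
      }
      if (delta < tol) break
    }
    eta <- b0 + as.numeric(X %*% beta)
    if (max(abs(c(b0, beta) - oldB)) < tol) { converged <- TRUE; break }
  }
  list(b0 = b0, beta = beta, eta = eta, converged = converged)
}

#' Fit the Maxent-style penalized presence-background model
#'
#' A penalized, heavily weighted logistic regression: presences weight 1
#' against the background sample at weight 10,000, with an L1 penalty
#' `lambda_j = rm * beta_class(m) * s_j * sqrt(m)` on each feature
#' coefficient (`m` = presence count, `s_j` = the feature's standard
#' deviation at presences, `beta_class` the per-feature-class default
#' regularization interpolated over `m`), optimized by cyclic coordinate
#' descent. This exploits the mathematical correspondence between Maxent
#' and infinitely weighted logistic regression: at `rm = 0` the fit
#' coincides with the unpenalized weighted GLM. The raw output is the
#' normalized exponential of the feature score, summing to 1 over the
#' training presences-plus-background set, from which the entropy `H`
#' used by the cloglog transform is computed. `k` counts non-zero
#' penalized coefficients (intercept excluded).
#'
#' @param presValues,bgValues data.frames of base variable values at
#'   presences and background points.
#' @param vars variable subset.
#' @param rtype response type.
#' @param rm regularization multiplier (one of 0.1/0.3/0.6/1/2.5/5 in the
#'   standard grid; 0 gives the unpenalized fit).
#' @param wPresence,wAbsence observation weights.
#' @param tol coordinate-descent convergence tolerance.
#' @return an [EnmModel-class]
#' @export
fitMaxent <- function(presValues, bgValues, vars, rtype, rm = 1,
                      wPresence = 1, wAbsence = 10000, tol = 1e-7) {
  np <- nrow(presValues)
  base <- rbind(as.matrix(as.data.frame(presValues)[vars]),
                as.matrix(as.data.frame(bgValues)[vars]))
  F <- buildFeatures(base, vars, rtype)
  y <- c(rep(1, np), rep(0, nrow(bgValues)))
  w <- c(rep(wPresence, np), rep(wAbsence, nrow(bgValues)))
  classOf <- attr(F, "class_of")
  sPres <- apply(F[seq_len(np), , drop = FALSE], 2, stats::sd)
  sPres[sPres == 0 | is.na(sPres)] <- 1
  lambda <- rm * vapply(classOf, betaDefault, numeric(1), m = np) *
    sPres * sqrt(np)
  flag <- ""
  if (np < ncol(F) + 5) flag <- "unstable: too few presences for features"
  fit <- penalizedLogisticCD(F, y, w, lambda, tol = tol)
  if (!fit$converged && flag == "")
    flag <- "failed: coordinate descent did not converge"
  if (max(abs(fit$beta)) > 20 && flag == "")
    flag <- "failed: apparent separation"
  beta <- c(`(Intercept)` = fit$b0,
            stats::setNames(fit$beta, colnames(F)))
  # raw distribution over training presences + background
  score <- as.numeric(F %*% fit$beta)
  logZ <- logSumExp(score)
  raw <- exp(score - logZ)
  H <- -sum(raw * log(pmax(raw, 1e-300)))
  ll <- weightedLogLik(y, w, stats::plogis(fit$eta))
  new("EnmModel", algorithm = "maxent", variables = vars,
      responseType = rtype, rm = rm,
      center = attr(F, "center"), scale = attr(F, "scale"),
      coef = beta, logLik = ll, entropy = H, logZ = logZ,
      k = sum(fit$beta != 0), converged = fit$converged, flag = flag)
}

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

setMethod("show", "EnmModel", function(object) {
  cat(sprintf("EnmModel [%s] vars={%s} type=%s%s  k=%d%s\n",
              object@algorithm, paste(object@variables, collapse = ","),
              object@responseType,
              if (is.na(object@rm)) "" else paste0(" rm=", object@rm),
              as.integer(object@k),
              if (nzchar(object@flag)) paste0("  <", object@flag, ">") else ""))
})

# linear predictor (feature score incl. intercept) on new base values
modelScore <- function(model, values) {
  F <- buildFeatures(values, model@variables, model@responseType,
                     center = model@center, scale = model@scale)
  miss <- setdiff(colnames(F), names(model@coef)[-1])
  if (length(miss)) stop("model lacks coefficients for: ",
                         paste(miss, collapse = ", "))
  as.numeric(model@coef[1] + F %*% model@coef[colnames(F)])
}

#' Predict suitability from a fitted model
#'
#' Output types:
#' * `prob` (glm default): logistic probability of the linear predictor;
#' * `raw` (maxent default): exponential feature score divided by the
#'   training normalizer, so the training set sums to 1 ("free
#'   extrapolation": scores are never clamped to the training range);
#' * `cloglog`: `1 - exp(-exp(H) * raw)`, clipped to \[0, 1\];
#' * `scaled01`: the algorithm's default output rescaled to min 0, max 1
#'   over the prediction extent (the standard presentation for GLM
#'   transfers).
#'
#' @param model an [EnmModel-class].
#' @param newdata a data.frame of base variable values or a
#'   [RasterStack-class] containing the model's variables.
#' @param type `"auto"`, `"prob"`, `"raw"`, `"cloglog"` or `"scaled01"`.
#' @return numeric vector (data.frame input) or [RasterLayer-class]
#'   (stack input)
#' @export
predictEnm <- function(model, newdata,
                       type = c("auto", "prob", "raw", "cloglog",
                                "scaled01")) {
  type <- match.arg(type)
  if (type == "auto")
    type <- if (model@algorithm == "maxent") "cloglog" else "prob"
  asStack <- methods::is(newdata, "RasterStack")
  if (asStack) {
    miss <- setdiff(model@variables, names(newdata@layers))
    if (length(miss)) stop("missing variable(s) in stack: ",
                           paste(miss, collapse = ", "))
    ok <- jointValidMask(rasterStack(newdata@grid,
                                     newdata@layers[model@variables]))
    vals <- as.data.frame(lapply(newdata@layers[model@variables],
                                 function(m) m[ok]))
  } else {
    miss <- setdiff(model@variables, names(as.data.frame(newdata)))
    if (length(miss)) stop("missing variable(s): ",
                           paste(miss, collapse = ", "))
    vals <- newdata
  }
  score <- modelScore(model, vals)
  out <- switch(type,
    prob = stats::plogis(score),
    raw = exp(score - model@coef[1] - model@logZ),
    cloglog = pmin(1, pmax(0, 1 - exp(-exp(model@entropy) *
                                        exp(score - model@coef[1] -
                                              model@logZ)))),
    scaled01 = {
      p <- if (model@algorithm == "maxent")
        pmin(1, pmax(0, 1 - exp(-exp(model@entropy) *
                                  exp(score - model@coef[1] - model@logZ))))
      else stats::plogis(score)
      rng <- range(p)
      if (diff(rng) == 0) rep(0, length(p)) else (p - rng[1]) / diff(rng)
    })
  if (type %in% c("raw", "cloglog") && model@algorithm != "maxent")
    stop("raw/cloglog outputs are defined for maxent models only")
  if (!asStack) return(out)
  v <- matrix(NA_real_, newdata@grid@nrows, newdata@grid@ncols)
  v[ok] <- out
  rasterLayer(paste0("suitability_", type), newdata@grid, v)
}
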
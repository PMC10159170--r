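test_that("feature expansion follows the response-type rule exactly", {
  d <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  expect_equal(colnames(buildFeatures(d, c("a", "b"), "q")),
               c("I(a^2)", "I(b^2)"))
  expect_equal(ncol(buildFeatures(d, c("a", "b", "c"), "lqp")), 9)
  # lp on k variables: k + k(k-1)/2 columns, k = 2..6
  set.seed(51)
  d6 <- as.data.frame(matrix(rnorm(40 * 6), ncol = 6,
                             dimnames = list(NULL, paste0("x", 1:6))))
  for (k in 2:6) {
    F <- buildFeatures(d6, paste0("x", 1:k), "lp")
    expect_equal(ncol(F), k + k * (k - 1) / 2)
    # enumeration oracle for the product block
    prods <- utils::combn(paste0("x", 1:k), 2,
                          function(p) paste0(p[1], ":", p[2]))
    expect_identical(colnames(F), c(paste0("x", 1:k), prods))
  }
  # squares/products computed after standardization
  F <- buildFeatures(d, c("a", "b"), "lqp")
  z <- (d$a - mean(d$a)) / sd(d$a)
  expect_equal(F[, "I(a^2)"], z^2)
  zb <- (d$b - mean(d$b)) / sd(d$b)
  expect_equal(F[, "a:b"], z * zb)
  d$flat <- 1
  expect_error(buildFeatures(d, c("a", "flat"), "lq"), "flat")
})

test_that("the weighted GLM matches an independent optimizer", {
  md <- modelData()
  set.seed(52)
  pres <- md$train[1:20, ]
  bg <- md$bg[1:200, ]
  m <- fitGLM(pres, bg, c("clim1", "clim2"), "lq")
  # independent general-purpose optimizer on the same weighted likelihood
  F <- buildFeatures(rbind(as.matrix(pres[c("clim1", "clim2")]),
                           as.matrix(bg[c("clim1", "clim2")])),
                     c("clim1", "clim2"), "lq")
  X <- cbind(1, F)
  y <- c(rep(1, 20), rep(0, 200))
  w <- c(rep(1, 20), rep(10000, 200))
  nll <- function(beta) {
    p <- plogis(as.numeric(X %*% beta))
    -sum(w * (y * log(pmax(p, 1e-15)) + (1 - y) * log(pmax(1 - p, 1e-15))))
  }
  grad <- function(beta) {
    p <- plogis(as.numeric(X %*% beta))
    -as.numeric(crossprod(X, w * (y - p)))
  }
  start <- c(qlogis(sum(w * y) / sum(w)), rep(0, ncol(X) - 1))
  opt <- optim(start, nll, grad, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(unname(m@coef), opt$par, tolerance = 1e-5)
  expect_equal(m@logLik, -opt$value, tolerance = 1e-8)

  # doubling all weights leaves the coefficients unchanged
  m2 <- fitGLM(pres, bg, c("clim1", "clim2"), "lq",
               wPresence = 2, wAbsence = 20000)
  expect_equal(m2@coef, m@coef, tolerance = 1e-6)

  # AIC bookkeeping: k counts all coefficients incl. intercept
  expect_equal(m@k, 5)
})

test_that("adding a pure-noise feature never lowers the training fit", {
  md <- modelData()
  set.seed(53)
  tr <- md$train
  tr$noise <- rnorm(nrow(tr))
  bg <- md$bg
  bg$noise <- rnorm(nrow(bg))
  base <- fitGLM(tr, bg, c("clim1", "clim2"), "lq")
  withNoise <- fitGLM(tr, bg, c("clim1", "clim2", "noise"), "lq")
  expect_gte(withNoise@logLik, base@logLik - 1e-6)
})

test_that("GLM coefficient signs recover a logistic-quadratic truth", {
  # the truth has negative quadratic terms on both truth layers
  hits <- vapply(1:10, function(s) {
    w <- makeWorld(worldConfig(seed = 300 + s,
                               grid = geoGrid(-10, 5, 1 / 6, 48, 96),
                               nPresences = 300))
    occ <- w$occurrences
    a <- bufferArea(occ, w$fine, 5)
    bg <- suppressWarnings(sampleBackground(a, w$fine, 20000,
                                            seed = s))
    vals <- extractValues(w$fine, occ)
    m <- fitGLM(vals, bg, c("clim1", "clim2"), "lq")
    all(m@coef[c("I(clim1^2)", "I(clim2^2)")] < 0) &&
      m@coef["clim1"] > 0 && m@coef["clim2"] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the penalized fit collapses to the GLM at rm = 0 and shrinks", {
  md <- modelData()
  glmFit <- fitGLM(md$train, md$bg, c("clim1", "clim2"), "lq")
  mx0 <- fitMaxent(md$train, md$bg, c("clim1", "clim2"), "lq", rm = 0)
  expect_lt(max(abs(mx0@coef - glmFit@coef)), 1e-4)

  # non-zero coefficient count is non-increasing across the rm grid
  ks <- vapply(c(0.1, 0.3, 0.6, 1.0, 2.5, 5.0), function(rm)
    fitMaxent(md$train, md$bg, c("clim1", "clim2", "clim3"), "lqp",
              rm = rm)@k, numeric(1))
  expect_true(all(diff(ks) <= 0))

  # an extreme multiplier zeroes everything: uniform raw, H = log N
  mxBig <- fitMaxent(md$train, md$bg, c("clim1", "clim2"), "lq", rm = 1e6)
  expect_true(all(mxBig@coef[-1] == 0))
  N <- nrow(md$train) + nrow(md$bg)
  raw <- predictEnm(mxBig, rbind(md$train[c("clim1", "clim2")],
                                 md$bg[c("clim1", "clim2")]), type = "raw")
  expect_equal(raw, rep(1 / N, N), tolerance = 1e-12)
  expect_equal(mxBig@entropy, log(N), tolerance = 1e-12)
  # and its intercept-only fitted probability is the weighted prevalence
  w <- c(rep(1, nrow(md$train)), rep(10000, nrow(md$bg)))
  y <- c(rep(1, nrow(md$train)), rep(0, nrow(md$bg)))
  expect_equal(plogis(mxBig@coef[["(Intercept)"]]), sum(w * y) / sum(w),
               tolerance = 1e-10)
})

test_that("maxent raw scores always sum to one over the training set", {
  md <- modelData()
  for (rm in c(0.3, 1, 5)) {
    mx <- fitMaxent(md$train, md$bg, c("clim1", "clim3"), "lq", rm = rm)
    raw <- predictEnm(mx, rbind(md$train[c("clim1", "clim3")],
                                md$bg[c("clim1", "clim3")]), type = "raw")
    expect_equal(sum(raw), 1, tolerance = 1e-9)
  }
})

test_that("prediction replays training standardization and transforms", {
  md <- modelData()
  m <- fitGLM(md$train, md$bg, c("clim1", "clim2"), "lqp")
  # training-table predictions equal the hand-computed linear predictor
  p <- predictEnm(m, md$train, type = "prob")
  i <- 7
  z1 <- (md$train$clim1[i] - m@center[["clim1"]]) / m@scale[["clim1"]]
  z2 <- (md$train$clim2[i] - m@center[["clim2"]]) / m@scale[["clim2"]]
  eta <- m@coef[["(Intercept)"]] + m@coef[["clim1"]] * z1 +
    m@coef[["clim2"]] * z2 + m@coef[["I(clim1^2)"]] * z1^2 +
    m@coef[["I(clim2^2)"]] * z2^2 + m@coef[["clim1:clim2"]] * z1 * z2
  expect_equal(p[i], plogis(eta), tolerance = 1e-12)

  # scaled01 spans exactly [0, 1]
  s01 <- predictEnm(m, md$bg, type = "scaled01")
  expect_equal(range(s01), c(0, 1))

  # cloglog is a monotone transform of raw
  mx <- fitMaxent(md$train, md$bg, c("clim1", "clim2"), "lq", rm = 1)
  raw <- predictEnm(mx, md$bg, type = "raw")
  cl <- predictEnm(mx, md$bg, type = "cloglog")
  expect_equal(cor(raw, cl, method = "spearman"), 1)
  expect_true(all(cl >= 0 & cl <= 1))

  # raster input returns a layer; missing variables are named
  lyr <- predictEnm(mx, testWorld()$fine, type = "cloglog")
  expect_s4_class(lyr, "RasterLayer")
  expect_error(predictEnm(mx, md$bg[, c("lon", "lat")], type = "raw"),
               "clim1")
  expect_error(predictEnm(m, md$bg, type = "raw"), "maxent")
})
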
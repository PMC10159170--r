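test_that("candidate enumeration matches brute-force subset counting", {
  # pool of 3, glm: (C(3,2) + C(3,3)) * 5 = 20, verified by listing
  c3 <- enumerateCandidates(c("a", "b", "c"), "glm")
  expect_equal(nrow(c3), 20)
  expect_setequal(unique(c3$subset), c("a,b", "a,c", "b,c", "a,b,c"))
  expect_true(all(table(c3$subset) == 5))
  expect_true(all(is.na(c3$rm)))

  # the (2^V - V - 1) closed form against explicit enumeration, V <= 8
  for (V in 2:8) {
    pool <- paste0("v", seq_len(V))
    nSub <- sum(vapply(2:V, function(k) choose(V, k), numeric(1)))
    expect_equal(nSub, 2^V - V - 1)
    expect_equal(nrow(enumerateCandidates(pool, "glm")), nSub * 5)
    expect_equal(nrow(enumerateCandidates(pool, "maxent")), nSub * 30)
  }
  # deterministic order
  expect_identical(enumerateCandidates(letters[1:4], "maxent"),
                   enumerateCandidates(letters[1:4], "maxent"))
  expect_error(enumerateCandidates("a", "glm"), "pool smaller")
})

test_that("occurrence splits are seeded, disjoint and exhaustive", {
  occ <- occTable(runif(100), runif(100))
  sp <- splitOccurrences(occ, 0.5, seed = 3)
  expect_equal(nOcc(sp$train), 50)
  expect_equal(nOcc(sp$test), 50)
  expect_length(intersect(sp$train@records$id, sp$test@records$id), 0)
  expect_setequal(c(sp$train@records$id, sp$test@records$id), 1:100)
  sp2 <- splitOccurrences(occ, 0.5, seed = 3)
  expect_identical(sp$train@records, sp2$train@records)
  # fraction 1: empty test set
  sp3 <- splitOccurrences(occ, 1, seed = 1)
  expect_equal(nOcc(sp3$test), 0)
})

test_that("the omission threshold admits E% of training presences", {
  set.seed(61)
  train <- runif(200)
  om <- omissionRate(train, train, E = 0.05)
  expect_lte(om$rate, 0.05 + 1 / 200)
  # constant predictions: nothing falls strictly below the threshold
  omc <- omissionRate(rep(0.4, 50), rep(0.4, 500))
  expect_equal(omc$rate, 0)
  # large-sample calibration: test drawn from the training distribution
  trainBig <- rnorm(5000)
  testBig <- rnorm(5000)
  omb <- omissionRate(trainBig, testBig, E = 0.05)
  expect_lt(abs(omb$rate - 0.05), 0.02)
})

test_that("AICc arithmetic and the uniform-model closed form hold", {
  expect_equal(aicc(3, 20, -100), 207.5)
  expect_equal(aicc(3, 20, -100), 2 * 3 + 200 + 24 / 16)
  expect_true(is.na(aicc(5, 6, -10)))

  # uniform raw over N cells: lnL = -n log N at k = 0
  md <- modelData()
  w <- testWorld()
  a <- md$area
  masked <- maskStack(w$fine, a)
  mxBig <- fitMaxent(md$train, md$bg, c("clim1", "clim2"), "lq", rm = 1e6)
  aw <- aiccWarren(mxBig, masked, md$occ)
  N <- sum(nichesift:::jointValidMask(masked))
  expect_equal(aw$k, 0)
  expect_equal(aw$logLik, -nOcc(md$occ) * log(N), tolerance = 1e-9)

  # general model: AICc matches recomputation from the exported raw raster
  mx <- fitMaxent(md$train, md$bg, c("clim1", "clim2"), "lq", rm = 1)
  aw2 <- aiccWarren(mx, masked, md$occ)
  rawLayer <- predictEnm(mx, masked, type = "raw")
  v <- rawLayer@values / sum(rawLayer@values, na.rm = TRUE)
  rc <- nichesift:::cellFromXY(masked@grid, md$occ@records$lon,
                               md$occ@records$lat)
  lnL <- sum(log(v[cbind(rc$row, rc$col)]))
  n <- nOcc(md$occ)
  k <- mx@k
  expect_equal(aw2$aicc, 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-9)
})

test_that("partial ROC separates informative from uninformative models", {
  w <- testWorld()
  truth <- w$truth
  valid <- !is.na(truth@values)
  set.seed(62)
  # the truth itself as the prediction: strong signal
  occ <- sampleOccurrences(truth, 100, seed = 63)
  rc <- nichesift:::cellFromXY(truth@grid, occ@records$lon,
                               occ@records$lat)
  presPred <- truth@values[cbind(rc$row, rc$col)]
  bgPred <- sample(truth@values[valid], 4000)
  pr <- partialROC(presPred, bgPred, seed = 64)
  expect_gt(pr$meanRatio, 1)
  expect_lt(pr$p, 0.05)

  # a perfectly separating model: presences rank far above background
  sharp <- partialROC(runif(100, 0.8, 1), runif(5000), seed = 66)
  expect_gt(sharp$meanRatio, 1.5)
  expect_lt(sharp$p, 0.05)

  # uninformative predictions: ratio near 1, not significant
  nullPr <- partialROC(runif(100), runif(5000), seed = 65)
  expect_lt(abs(nullPr$meanRatio - 1), 0.15)
  expect_gte(nullPr$p, 0.05)

  # degenerate constant predictions
  flat <- partialROC(rep(0.5, 50), rep(0.5, 1000), seed = 1)
  expect_true(flat$degenerate)
  expect_equal(flat$p, 1)
})

test_that("the selection rule keeps significant, accurate, parsimonious models", {
  # hand-built table of six candidates
  tab <- data.frame(
    id = 1:6,
    proc_p   = c(0.00, 0.00, 0.20, 0.01, 0.00, NA),
    omission = c(0.02, 0.04, 0.01, 0.30, 0.05, 0.01),
    aic      = c(100,  101.5, 99,  98,   104,  90),
    flag     = c("", "", "", "", "", "failed: x"))
  out <- selectModels(tab)
  # manual trace: candidates 1, 2, 5 pass both screens; best AIC 100 ->
  # deltas 0, 1.5, 4 -> selected = 1, 2
  expect_equal(out$selected, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$delta_aic[1:2], c(0, 1.5))
  expect_equal(min(out$delta_aic[out$selected]), 0)

  # single candidate passing both screens
  one <- selectModels(tab[1, ])
  expect_true(one$selected)
  expect_equal(one$delta_aic, 0)

  # tightening the omission cutoff never enlarges the selection
  tab2 <- tab
  tab2$omission[1] <- 0.005
  loose <- selectModels(tab2, omMax = 0.05)
  tight <- selectModels(tab2, omMax = 0.01)
  expect_true(all(which(tight$selected) %in% which(loose$selected)))
  expect_lte(sum(tight$selected), sum(loose$selected))

  # fallback: nothing passes omission -> delta AIC among significant
  tabBad <- transform(tab[1:5, ], omission = 0.5)
  expect_warning(fb <- selectModels(tabBad), "falling back")
  expect_true(any(fb$selected))
  expect_error(selectModels(data.frame(proc_p = 1, omission = 1,
                                       aic = NA, flag = "failed")),
               "all candidates failed")
})

test_that("a treatment runs the full loop deterministically", {
  w <- testWorld()
  occ <- thinOccurrences(w$occurrences, 15, seed = 6)
  a <- bufferArea(occ, w$fine, 5)
  tr <- runTreatment(c("clim1", "clim2", "clim3", "clim4"), "glm", occ, a,
                     w$fine, label = "demo", seed = 17)
  # 4-variable pool: (C(4,2) + C(4,3) + C(4,4)) * 5 = 55 candidates
  expect_equal(nrow(tr$results), 55)
  expect_s4_class(tr$final, "EnmModel")
  expect_true(all(tr$winnerVariables %in% c("clim1", "clim2", "clim3",
                                            "clim4")))
  expect_equal(min(tr$results$delta_aic[tr$results$selected]), 0)
  # rerun with identical seeds reproduces the winner exactly
  tr2 <- runTreatment(c("clim1", "clim2", "clim3", "clim4"), "glm", occ, a,
                      w$fine, label = "demo", seed = 17)
  expect_identical(tr$winnerVariables, tr2$winnerVariables)
  expect_identical(tr$results, tr2$results)
})
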
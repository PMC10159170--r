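# a fitted maxent model plus its training data, shared across tests
reportFit <- function() {
  cached("reportFit", function() {
    md <- modelData()
    m <- fitMaxent(md$train, md$bg, c("clim1", "clim2", "clim5"), "lq",
                   rm = 1)
    list(md = md, m = m)
  })
}

test_that("jackknife importance ranks the dominant variable first", {
  # a world whose truth depends on one layer only
  oneTruth <- makeWorld(worldConfig(
    seed = 77, grid = geoGrid(-10, 5, 1 / 6, 48, 96), nPresences = 250,
    truthTerms = data.frame(layer = "clim1", linear = 1.5, quad = -1.5),
    nDecoys = 2L, nClimate = 4L))
  occ1 <- oneTruth$occurrences
  bg1 <- suppressWarnings(sampleBackground(
    bufferArea(occ1, oneTruth$fine, 5), oneTruth$fine, 3000, seed = 70))
  tr1 <- extractValues(oneTruth$fine, occ1)
  m1 <- fitMaxent(tr1, bg1, c("clim1", "clim4"), "lq", rm = 1)
  jk1 <- jackknifeImportance(m1, tr1, bg1, seed = 71)
  expect_equal(jk1$variable[which.max(jk1$gain_only)], "clim1")
  expect_gt(jk1$permutation_importance[jk1$variable == "clim1"],
            jk1$permutation_importance[jk1$variable == "clim4"])

  rf <- reportFit()
  jk <- jackknifeImportance(rf$m, rf$md$train, rf$md$bg, seed = 71)
  expect_equal(sum(jk$contribution), 1, tolerance = 1e-9)
  # truth variables outrank the independent nuisance layer clim5
  expect_gt(min(jk$gain_only[jk$variable %in% c("clim1", "clim2")]),
            jk$gain_only[jk$variable == "clim5"])
  # nesting: a single variable cannot out-gain the full model
  expect_lte(max(jk$gain_only), attr(jk, "gain_full") + 0.05)

  # a perfect duplicate variable has near-zero exclusion drop
  md <- reportFit()$md
  tr <- md$train; bg <- md$bg
  tr$dup <- tr$clim1; bg$dup <- bg$clim1
  mDup <- fitMaxent(tr, bg, c("clim1", "dup", "clim2"), "lq", rm = 1)
  jkDup <- jackknifeImportance(mDup, tr, bg, seed = 72)
  full <- attr(jkDup, "gain_full")
  expect_lt(full - jkDup$gain_without[jkDup$variable == "clim1"], 0.02)
  expect_lt(full - jkDup$gain_without[jkDup$variable == "dup"], 0.02)
  expect_error(jackknifeImportance(fitGLM(md$train, md$bg,
                                          c("clim1", "clim2"), "lq"),
                                   md$train, md$bg), "maxent")
})

test_that("sequential deviance components add up and test noise fairly", {
  rf <- reportFit()
  md <- rf$md
  g <- fitGLM(md$train, md$bg, c("clim1", "clim2"), "lq")
  dt <- devianceTable(g, md$train, md$bg)
  expect_equal(dt$term[1], "NULL")
  nullDev <- dt$resid_deviance[1]
  residDev <- dt$resid_deviance[nrow(dt)]
  expect_equal(sum(dt$deviance[-1]), nullDev - residDev, tolerance = 1e-8)
  expect_true(all(dt$df[-1] == 1))

  # p-values of a pure-noise term are uniform under the null
  set.seed(73)
  ps <- vapply(1:50, function(s) {
    n <- 120
    dat <- data.frame(x = rnorm(n + 400), noise = rnorm(n + 400))
    pres <- dat[seq_len(n), ]
    bg <- dat[-seq_len(n), ]
    # x drives the truth; noise does not
    keepP <- plogis(1.5 * pres$x) > runif(n)
    gm <- fitGLM(pres[keepP, , drop = FALSE], bg, c("x", "noise"), "lq")
    d <- devianceTable(gm, pres[keepP, , drop = FALSE], bg)
    d$p[d$term == "I(noise^2)"]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_error(devianceTable(rf$m, md$train, md$bg), "glm")
})

test_that("projections transfer, rescale and summarize disagreement", {
  w <- testWorld()
  occ <- thinOccurrences(w$occurrences, 20, seed = 7)
  a1 <- bufferArea(occ, w$fine, 4)
  a2 <- concaveArea(occ, w$fine, alpha = Inf, radius = 4)
  t1 <- suppressWarnings(
    runTreatment(c("clim1", "clim2"), "glm", occ, a1, w$fine,
                 label = "t1", seed = 31))
  t2 <- suppressWarnings(
    runTreatment(c("clim1", "clim2"), "maxent", occ, a2, w$fine,
                 label = "t2", seed = 32, rms = c(0.5, 1)))
  pj <- projectAll(list(t1, t2), list(a1, a2), w$fine)
  expect_s4_class(pj$variability, "RasterLayer")
  expect_identical(layerNames(pj$projections), c("t1", "t2"))
  # glm transfer is rescaled to [0, 1]
  v1 <- pj$projections@layers$t1
  expect_equal(range(v1, na.rm = TRUE), c(0, 1))
  # projection over the union reproduces training-time predictions where
  # the model was calibrated (determinism of predict)
  direct <- predictEnm(t2$final, maskStack(w$fine, a2), type = "cloglog")
  both <- !is.na(direct@values) & !is.na(pj$projections@layers$t2)
  expect_equal(pj$projections@layers$t2[both], direct@values[both])
  # identical treatments disagree nowhere
  t1b <- t1
  t1b$label <- "t1b"
  pj2 <- projectAll(list(t1, t1b), list(a1), w$fine)
  expect_true(all(pj2$variability@values[!is.na(pj2$variability@values)]
                  == 0))
})

test_that("environmental-space export mirrors the prediction table", {
  w <- testWorld()
  occ <- thinOccurrences(w$occurrences, 20, seed = 8)
  a <- bufferArea(occ, w$fine, 4)
  tr <- suppressWarnings(
    runTreatment(c("clim1", "clim2"), "glm", occ, a, w$fine,
                 label = "env", seed = 33))
  pred <- predictEnm(tr$final, maskStack(w$fine, a), type = "prob")
  tab <- envSpaceExport(pred, w$fine, c("clim1", "clim2", "clim3"),
                        threshold = tr$threshold)
  expect_equal(nrow(tab), sum(!is.na(pred@values)))
  expect_identical(tab$above, tab$suitability >= tr$threshold)
  # flagged (suitable) cells sit at higher truth suitability on average
  expect_gt(mean(w$truth@values[tab$cell[tab$above]]),
            mean(w$truth@values[tab$cell[!tab$above]]))
  expect_error(envSpaceExport(pred, w$fine, c("clim1", "nope", "clim3"),
                              0.5), "nope")
  expect_error(envSpaceExport(pred, w$fine, c("clim1", "clim2"), 0.5),
               "three")
})

test_that("the consistency matrix tallies winners across treatments", {
  cm <- consistencyMatrix(list(t1 = c("A", "B")),
                          variables = c("A", "B", "C"))
  expect_equal(unname(cm$matrix[, "t1"]), c(TRUE, TRUE, FALSE))
  expect_equal(unname(cm$frequency), c(1, 1, 0))

  winners <- list(t1 = c("A", "B"), t2 = c("A"), t3 = NULL,
                  t4 = c("A", "C"))
  cm2 <- consistencyMatrix(winners, variables = c("A", "B", "C", "D"))
  expect_equal(cm2$nTreatments, 3)            # failed t3 excluded
  expect_true(all(is.na(cm2$matrix[, "t3"])))
  expect_equal(unname(cm2$frequency),
               c(1, 1 / 3, 1 / 3, 0))          # D never selected
  # invariance to treatment ordering
  cm3 <- consistencyMatrix(winners[c(4, 2, 1, 3)],
                           variables = c("A", "B", "C", "D"))
  expect_equal(cm3$frequency, cm2$frequency)
  expect_output(print(cm2), "ConsistencyMatrix")
})
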
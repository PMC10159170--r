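test_that("cleaning drops (0,0), duplicates, missing coords and old years", {
  raw <- data.frame(
    lon  = c(10.0, 11.0,  0.0, 12.5, 10.0, 12.0),
    lat  = c(50.0, 51.0,  0.0,   NA, 50.0, 52.0),
    year = c(2000, 1950, 2001, 2002, 2005, 2010),
    source = "t")
  out <- cleanOccurrences(occurrenceSet(raw), minYear = 1970)
  # hand count: row 2 (pre-1970), row 3 ((0,0)), row 4 (missing lat) and
  # row 5 (duplicate of row 1) are removed -> rows 1 and 6 survive? row 5
  # duplicates row 1's coordinates, so 3 distinct fates -> 2 survivors
  expect_equal(out@records$lon, c(10.0, 12.0))
  # survivors keep their original order
  r2 <- data.frame(lon = c(3, 1, 2), lat = c(3, 1, 2), year = 2000)
  expect_equal(cleanOccurrences(occurrenceSet(r2))@records$lon, c(3, 1, 2))
  # a record at exactly (0,0) is removed even with valid year
  expect_equal(nOcc(cleanOccurrences(occTable(0, 0))), 0)
  # identical rows collapse to one
  expect_equal(nOcc(cleanOccurrences(occTable(c(5, 5), c(5, 5)))), 1)
  # missing coordinate columns are a schema error
  expect_error(cleanOccurrences(data.frame(x = 1)), "lon")
  # status filtering is off by default, on when asked
  st <- data.frame(lon = 1:3, lat = 1:3, status = c("present", "absent",
                                                    "uncommon"))
  expect_equal(nOcc(cleanOccurrences(st)), 3)
  expect_equal(nOcc(cleanOccurrences(st, statusColumn = "status")), 1)
})

test_that("snapping moves near-edge points to the nearest valid centre", {
  # 1x3 grid of 2' cells with only the middle cell valid
  cs <- 2 / 60
  g <- geoGrid(0, cs, cs, 1, 3)
  st <- rasterStack(g, list(a = matrix(c(NA, 5, NA), 1)))
  mid <- c(1.5 * cs, 0.5 * cs)   # centre of the valid cell

  # already-valid point is unchanged
  out <- snapToValid(occTable(mid[1] + 0.3 * cs, mid[2]), st, maxDist = 5)
  expect_equal(out@records$lon, mid[1] + 0.3 * cs)
  expect_equal(nrow(attr(out, "snapLog")), 0)

  # point on the nodata cell, ~3' from the valid centre, snaps onto it
  out2 <- snapToValid(occTable(mid[1] + 3 / 60, mid[2]), st, maxDist = 5)
  expect_equal(out2@records$lon, mid[1])
  expect_equal(out2@records$lat, mid[2])
  expect_equal(attr(out2, "snapLog")$action, "moved")

  # a point farther than maxDist is dropped, and reported
  out3 <- snapToValid(occTable(mid[1] + 10 / 60, mid[2]), st, maxDist = 5)
  expect_equal(nOcc(out3), 0)
  expect_equal(attr(out3, "snapLog")$action, "dropped")

  # random nodata-adjacent points match a brute-force nearest search
  set.seed(12)
  w <- testWorld()
  stH <- w$fine
  stH@layers <- lapply(stH@layers, function(v) { v[, 1:30] <- NA; v })
  pts <- data.frame(lon = runif(15, -5.2, -4.9), lat = runif(15, 0, 4))
  snapped <- snapToValid(occurrenceSet(pts), stH, maxDist = 8)
  ctr <- nichesift:::cellCenters(stH@grid)
  ok <- nichesift:::jointValidMask(stH)
  vLon <- ctr$lon[ok]; vLat <- ctr$lat[ok]
  rc <- nichesift:::cellFromXY(stH@grid, pts$lon, pts$lat)
  for (i in seq_len(nrow(pts))) {
    onValid <- !rc$outside[i] && ok[rc$row[i], rc$col[i]]
    k <- which(snapped@records$id == i)
    if (onValid) {
      expect_equal(snapped@records$lon[k], pts$lon[i])
    } else {
      d <- nichesift:::gcAngle(pts$lon[i], pts$lat[i], vLon, vLat) * 60
      j <- which.min(d)
      if (d[j] <= 8) {
        expect_equal(c(snapped@records$lon[k], snapped@records$lat[k]),
                     c(vLon[j], vLat[j]))
      } else {
        expect_length(k, 0)
      }
    }
  }
})

test_that("thinning enforces the distance and is maximal and idempotent", {
  # two points 10' apart: one survives
  two <- occTable(c(0, 10 / 60), c(0, 0))
  expect_equal(nOcc(thinOccurrences(two, 30, seed = 1)), 1)

  # 1-degree lattice survives 30' thinning intact
  gridPts <- expand.grid(lon = 0:4, lat = 50:54)
  lat5 <- occTable(gridPts$lon, gridPts$lat)
  expect_equal(nOcc(thinOccurrences(lat5, 30, seed = 2)), 25)

  # random cloud: all-pairs >= min distance, and maximality
  set.seed(13)
  occ <- occTable(runif(200, 0, 3), runif(200, 40, 43))
  th <- thinOccurrences(occ, 30, seed = 3)
  r <- th@records
  d <- nichesift:::gcAngleMatrix(r$lon, r$lat, r$lon, r$lat) * 60
  diag(d) <- Inf
  expect_true(all(d >= 30))
  dropped <- occ@records[!occ@records$id %in% r$id, ]
  dAll <- nichesift:::gcAngleMatrix(dropped$lon, dropped$lat,
                                    r$lon, r$lat) * 60
  expect_true(all(apply(dAll, 1, min) < 30))

  # idempotence at the same distance
  again <- thinOccurrences(th, 30, seed = 99)
  expect_equal(nOcc(again), nOcc(th))
  expect_error(thinOccurrences(occ, 0), "positive")
  expect_equal(nOcc(thinOccurrences(occTable(numeric(0), numeric(0)), 30)),
               0)
})

test_that("Moran's I matches the double-sum definition and its null", {
  set.seed(14)
  pts <- occTable(runif(25, 0, 2), runif(25, 10, 12))
  x <- rnorm(25)
  nb <- 90
  got <- moransI(x, pts, nb)
  # explicit double-sum oracle
  r <- pts@records
  n <- 25
  w <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    dij <- nichesift:::gcAngle(r$lon[i], r$lat[i], r$lon[j], r$lat[j]) * 60
    if (i != j && dij <= nb) w[i, j] <- 1
  }
  num <- 0
  xb <- mean(x)
  for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
  oracle <- (n / sum(w)) * num / sum((x - xb)^2)
  expect_equal(got$observed, oracle, tolerance = 1e-12)
  expect_equal(got$expected, -1 / 24)

  # permutation null: mean observed I over shuffles approaches E[I]
  perms <- replicate(400, moransI(sample(x), pts, nb)$observed)
  expect_lt(abs(mean(perms) - (-1 / 24)), 0.02)

  # affine invariance
  expect_equal(moransI(3 * x - 7, pts, nb)$observed, got$observed,
               tolerance = 1e-12)

  # contract cases
  expect_false(moransI(rep(1, 25), pts, nb)$defined)
  expect_false(moransI(x, pts, 1e-6)$defined)
  expect_error(moransI(x[1:2], occTable(1:2, 1:2), nb), "3 points")
})

test_that("the thinning-distance scan behaves monotonically", {
  w <- testWorld()
  occ <- w$occurrences
  scan <- thinningScan(occ, rasterStack(w$fine@grid,
                                        w$fine@layers[c("clim1", "clim2")]),
                       distances = c(0, 15, 30, 60), seed = 4)
  expect_equal(scan$n_retained[1], nOcc(occ))
  expect_true(all(diff(scan$n_retained) <= 0))
  # on smooth fields, autocorrelation declines as thinning distance grows
  rho <- cor(scan$distance, scan$clim1, method = "spearman")
  expect_lt(rho, 0)
})
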
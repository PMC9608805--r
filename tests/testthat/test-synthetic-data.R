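test_that("driver generation is seeded, shaped, and controls autocorrelation", {
  g <- GridSpec(50, 50)
  a <- generateDrivers(g, nDrivers = 3, smoothness = 2, seed = 11)
  b <- generateDrivers(g, nDrivers = 3, smoothness = 2, seed = 11)
  expect_identical(driverLayers(a), driverLayers(b))
  expect_length(driverLayers(a), 3L)
  expect_identical(dim(driverLayers(a)[[1]]), c(50L, 50L))

  # smoothness 0: i.i.d. noise, lag-1 autocorrelation near zero at 1e4 cells
  iid <- generateDrivers(GridSpec(100, 100), 1, smoothness = 0, seed = 3)
  m <- driverLayers(iid)[[1]]
  r <- cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))
  expect_lt(abs(r), 0.05)

  # smoothing induces strong positive lag-1 autocorrelation
  sm <- generateDrivers(GridSpec(100, 100), 1, smoothness = 3, seed = 3)
  ms <- driverLayers(sm)[[1]]
  expect_gt(cor(as.vector(ms[-1, ]), as.vector(ms[-nrow(ms), ])), 0.5)

  expect_error(generateDrivers(g, nDrivers = 0), "nDrivers")
})

test_that("landscape pairs honour exact transition bookkeeping and restriction", {
  cfg <- SynthConfig(seed = 42)
  scene <- generateLandscapePair(cfg)
  tt <- transitionTable(scene@luT0, scene@luT1)
  for (i in seq_len(nrow(cfg$transitionCounts))) {
    tc <- cfg$transitionCounts[i, ]
    expect_equal(unname(tt[tc$from, tc$to]), tc$count)
  }
  # no transitions other than the configured ones
  off <- sum(tt) - sum(diag(tt))
  expect_equal(off, sum(cfg$transitionCounts$count))
  # restricted cells never change
  changed <- rasterData(scene@luT0) != rasterData(scene@luT1)
  expect_equal(sum(changed & scene@restriction == 1L), 0L)

  # all-zero transitions: identical rasters
  cfg0 <- SynthConfig(transitionCounts = data.frame(from = 1L, to = 6L,
                                                    count = 0L), seed = 1)
  sc0 <- generateLandscapePair(cfg0)
  expect_identical(rasterData(sc0@luT0), rasterData(sc0@luT1))

  # infeasible demand names the offending pair
  bad <- SynthConfig(transitionCounts = data.frame(from = 2L, to = 6L,
                                                   count = 100000L))
  expect_error(generateLandscapePair(bad), "2->6")
})

test_that("strong driver effects leave a recoverable footprint in the changes", {
  cfg <- SynthConfig(grid = GridSpec(100, 100),
                     transitionCounts = data.frame(from = c(1L, 3L),
                                                   to = c(6L, 6L),
                                                   count = c(300L, 300L)),
                     driverEffect = c(driver1 = 4, driver2 = 0.3,
                                      driver3 = 0.3),
                     restrictionFraction = 0.1, seed = 5)
  scene <- generateLandscapePair(cfg)
  changed <- as.numeric(rasterData(scene@luT0) != rasterData(scene@luT1))
  d1 <- as.vector(driverLayers(scene@drivers)$driver1)
  expect_gt(cor(d1, changed), 0.3)
})

test_that("zone tessellations partition the grid deterministically", {
  g <- GridSpec(100, 100)
  z <- generateZones(g, 25, seed = 8)
  expect_identical(sort(unique(as.vector(rasterData(z)))), 1:25)
  expect_equal(sum(zonalSum(matrix(1, 100, 100), z)$value_km2),
               100 * 100 * cellAreaKm2(g))
  z2 <- generateZones(g, 25, seed = 8)
  expect_identical(rasterData(z), rasterData(z2))
  expect_error(generateZones(g, 1), "nZones")
  expect_error(generateZones(GridSpec(2, 2), 5), "nZones")
})

test_that("zero-noise socio-economic history reproduces the forward run exactly", {
  p <- SDParams()
  sc <- ScenarioSpec("hist", 0.09, 0.003)
  h <- suppressWarnings(generateSDHistory(p, sc, nYears = 8, noiseSd = 0, seed = 4))
  traj <- suppressWarnings(runScenario(p, sc, p@baseYear + 7L))
  expect_identical(h$construction, traj$construction)
  expect_identical(h$gdp, traj$gdp)
  # noise: different seeds differ, same length; negative sd rejected
  h1 <- suppressWarnings(generateSDHistory(p, sc, 8, noiseSd = 10, seed = 1))
  h2 <- suppressWarnings(generateSDHistory(p, sc, 8, noiseSd = 10, seed = 2))
  expect_equal(nrow(h1), nrow(h2))
  expect_false(identical(h1$total_population, h2$total_population))
  expect_error(suppressWarnings(generateSDHistory(p, sc, 8, noiseSd = -1)), "noiseSd")
})
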
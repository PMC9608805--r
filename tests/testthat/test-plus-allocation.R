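test_that("driver normalization is min-max, idempotent, and rejects constants", {
  g <- GridSpec(2, 3)
  st <- DriverStack(list(a = matrix(c(5, 10, 15, 5, 5, 15), 2, 3),
                         b = matrix(c(2, 4, 8, 2, 2, 8), 2, 3)), g)
  nm <- normalizeDrivers(st)
  expect_equal(driverLayers(nm)$a[2, 1], 0.5)
  expect_equal(sort(unique(as.vector(driverLayers(nm)$b))), c(0, 1/3, 1))
  expect_identical(normalizeDrivers(nm), nm)
  cst <- DriverStack(list(flat = matrix(7, 2, 3)), g)
  expect_error(normalizeDrivers(cst), "flat")
})

test_that("expansion sampling counts positives from the generator truth", {
  cfg <- SynthConfig(transitionCounts = data.frame(from = 1L, to = 6L,
                                                   count = 40L), seed = 3)
  scene <- generateLandscapePair(cfg)
  s <- extractExpansionSamples(scene@luT0, scene@luT1, sampleRate = 1, seed = 1)
  expect_named(s, "6")
  expect_equal(sum(s[["6"]]$label == 1L), 40L)
  expect_equal(sum(s[["6"]]$label == 0L), 40L)  # balanced negatives
  s2 <- extractExpansionSamples(scene@luT0, scene@luT1, 0.5, seed = 9)
  s3 <- extractExpansionSamples(scene@luT0, scene@luT1, 0.5, seed = 9)
  expect_equal(sum(s2[["6"]]$label == 1L), 20L)
  expect_identical(s2, s3)
  expect_error(extractExpansionSamples(scene@luT0, scene@luT0, 1, 1),
               "identical")
})

test_that("the expansion classifier separates separable data and not permuted labels", {
  set.seed(7)
  g <- GridSpec(30, 30)
  x <- matrix(runif(900), 30, 30)
  drv <- DriverStack(list(driver1 = x), g, normalized = TRUE)
  # positives are exactly the high-x cells: perfectly separable
  pos <- order(as.vector(x), decreasing = TRUE)[1:60]
  neg <- order(as.vector(x))[1:60]
  ss <- structure(list("6" = data.frame(cell = c(pos, neg),
                                        label = rep(1:0, each = 60))),
                  class = "SampleSet")
  pot <- fitExpansionModel(ss, drv, seed = 1)
  p <- as.vector(potentialSurface(pot, 6))
  # training-set ranking AUC = 1
  auc <- mean(outer(p[pos], p[neg], `>`) + 0.5 * outer(p[pos], p[neg], `==`))
  expect_equal(auc, 1)
  # permuted labels: held-out AUC collapses to chance
  set.seed(42)
  cells <- c(pos, neg)
  lab <- sample(rep(1:0, each = 60))
  trainIdx <- sample(120, 60)
  ssPerm <- structure(list("6" = data.frame(cell = cells[trainIdx],
                                            label = lab[trainIdx])),
                      class = "SampleSet")
  potPerm <- fitExpansionModel(ssPerm, drv, seed = 1)
  pp <- as.vector(potentialSurface(potPerm, 6))
  testIdx <- setdiff(seq_len(120), trainIdx)
  p1 <- pp[cells[testIdx][lab[testIdx] == 1]]
  p0 <- pp[cells[testIdx][lab[testIdx] == 0]]
  aucPerm <- mean(outer(p1, p0, `>`) + 0.5 * outer(p1, p0, `==`))
  expect_lt(abs(aucPerm - 0.5), 0.1)
  # importances normalized per class
  expect_equal(sum(driverContributions(pot)[["6"]]), 1)
})

test_that("neighbourhood effect matches hand counts and its closed forms", {
  # saturation: uniform class-k raster
  lu <- LandUseRaster(matrix(3L, 5, 5))
  expect_true(all(neighborhoodEffect(lu, 3, 3) == 1))
  # absence
  expect_true(all(neighborhoodEffect(lu, 4, 3) == 0))
  # isolated centre cell on a 5x5 grid: 1/9 in the 3x3 block around it
  m <- matrix(1L, 5, 5); m[3, 3] <- 2L
  ne <- neighborhoodEffect(LandUseRaster(m), 2, 3)
  expect_equal(ne[3, 3], 1 / 9)
  expect_equal(ne[2, 3], 1 / 9)
  expect_equal(ne[2, 2], 1 / 9)
  expect_equal(ne[1, 1], 0)
  # truncated corner window of the uniform raster still saturates to 1
  expect_error(neighborhoodEffect(lu, 3, 4), "odd")
})

test_that("allocation with no decay and flat neighbourhood equals the ranking oracle", {
  set.seed(31)
  g <- GridSpec(20, 20)
  lu <- LandUseRaster(matrix(1L, 20, 20), g)
  lu@data[1:40] <- 6L
  P <- matrix(runif(400), 20, 20)
  pot <- makePotentials(list("6" = P), g)
  areas <- areasFromRaster(lu)
  demand <- areas
  demand[["construction"]] <- demand[["construction"]] + 5 * cellAreaKm2(g)
  demand[["cultivated"]] <- demand[["cultivated"]] - 5 * cellAreaKm2(g)
  cfg <- CarsConfig(initialThreshold = 0,
                    neighborhoodWeights = stats::setNames(rep(0, 7),
                                                          names(landClasses())),
                    seed = 5)
  sim <- carsSimulate(lu, pot, demand, restriction = NULL, cfg = cfg)
  converted <- which(rasterData(sim) != rasterData(lu))
  # oracle: the 5 eligible (class-1) cells with the highest potential
  eligible <- which(lu@data == 1L)
  oracle <- eligible[order(P[eligible], decreasing = TRUE)][1:5]
  expect_setequal(converted, oracle)
  expect_true(all(rasterData(sim)[converted] == 6L))
})

test_that("allocation meets demand, honours restrictions and transition rules, and is reproducible", {
  reps <- 25
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    n <- 30
    g <- GridSpec(n, n)
    lu <- LandUseRaster(matrix(sample(c(1L, 3L, 6L), n * n, replace = TRUE,
                                      prob = c(0.5, 0.4, 0.1)), n, n), g)
    restr <- matrix(rbinom(n * n, 1, 0.2), n, n)
    pot <- makePotentials(list("6" = matrix(runif(n * n), n, n),
                               "3" = matrix(runif(n * n), n, n)), g)
    areas <- areasFromRaster(lu)
    ca <- cellAreaKm2(g)
    shift <- sample(5:25, 1)
    demand <- areas
    demand[["construction"]] <- demand[["construction"]] + shift * ca
    demand[["forest"]] <- demand[["forest"]] + 3 * ca
    demand[["cultivated"]] <- demand[["cultivated"]] - (shift + 3) * ca
    tm <- matrix(TRUE, 7, 7)
    tm[3, 6] <- FALSE                     # forest may not become construction
    cfg <- CarsConfig(transitionMatrix = tm, seed = 2000 + r)
    sim <- carsSimulate(lu, pot, demand, restr, cfg)
    got <- areasFromRaster(sim)
    # mass balance within one cell per class
    expect_true(all(abs(got - demand) <= ca + 1e-12))
    # restriction invariance
    expect_true(all(rasterData(sim)[restr == 1L] == rasterData(lu)[restr == 1L]))
    # transition legality
    moved <- which(rasterData(sim) != rasterData(lu))
    expect_true(all(tm[cbind(rasterData(lu)[moved], rasterData(sim)[moved])]))
    # seeded bit-reproducibility
    sim2 <- carsSimulate(lu, pot, demand, restr, cfg)
    expect_identical(rasterData(sim), rasterData(sim2))
  }
})

test_that("map validation reproduces accuracy and kappa closed forms", {
  m1 <- LandUseRaster(matrix(c(rep(1L, 50), rep(2L, 50)), 10, 10))
  expect_equal(validateMap(m1, m1)$overall_accuracy, 1)
  expect_equal(validateMap(m1, m1)$kappa, 1)
  # confusion [[40,10],[10,40]] by construction
  a <- matrix(rep(c(1L, 2L), each = 50), 10, 10)
  b <- a
  b[1:10] <- 2L                         # 10 of the 1s called 2
  b[51:60] <- 1L                        # 10 of the 2s called 1
  v <- validateMap(LandUseRaster(b), LandUseRaster(a))
  expect_equal(v$overall_accuracy, 0.8)
  expect_equal(v$kappa, 0.6)
  # constant maps: degenerate marginals give kappa 0 by convention
  cst <- LandUseRaster(matrix(1L, 5, 5))
  expect_message(v0 <- validateMap(cst, cst), "degenerate")
  expect_equal(v0$kappa, 0)
})

test_that("areas are cell counts times cell area", {
  lu <- LandUseRaster(matrix(3L, 100, 100))  # default 10 m cells
  a <- areasFromRaster(lu)
  expect_equal(a[["forest"]], 1)
  expect_equal(a[["water"]], 0)
  expect_equal(sum(a), 1)
})

test_that("simulating the generated change with true demands recovers the map", {
  cfg <- SynthConfig(grid = GridSpec(50, 50),
                     driverEffect = c(driver1 = 5, driver2 = 0.3,
                                      driver3 = 0.3),
                     seed = 77)
  scene <- generateLandscapePair(cfg)
  s <- extractExpansionSamples(scene@luT0, scene@luT1, seed = 1)
  pot <- fitExpansionModel(s, normalizeDrivers(scene@drivers), seed = 2)
  sim <- carsSimulate(scene@luT0, pot, areasFromRaster(scene@luT1),
                      scene@restriction, CarsConfig(seed = 3))
  v <- validateMap(sim, scene@luT1)
  expect_gte(v$kappa, 0.8)
})
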
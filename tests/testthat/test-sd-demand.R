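test_that("stock integration is a plain annual Euler step", {
  expect_equal(integrateStock(100, 0), 100)
  expect_equal(integrateStock(583969, 0.0022), 585253.73, tolerance = 1e-8)
  # algebraic inverse returns the start value
  x <- integrateStock(1234.5, 0.08)
  expect_equal(integrateStock(x, -0.08 / 1.08), 1234.5)
})

test_that("construction demand is the anchored linear form, clamped at zero", {
  expect_equal(constructionDemand(162.05, 0, 0), 162.05)
  expect_equal(constructionDemand(162.05, 100000, 1e6), 164.427)
  expect_equal(constructionDemand(50, 123456, 654321,
                                  urpopCoeff = 0, investCoeff = 0), 50)
  expect_equal(constructionDemand(1, 1e9, 0), 0)  # clamp
})

test_that("scenario runs conserve area, are monotone, and order by growth rate", {
  p <- SDParams()
  scen <- standardScenarios()
  trajs <- lapply(scen, function(s)
    suppressWarnings(runScenario(p, s, 2035)))
  total0 <- sum(p@areas0)
  for (tr in trajs) {
    sums <- rowSums(tr[, names(landClasses())])
    expect_lt(max(abs(sums - total0)), 1e-6)
    expect_true(all(diff(tr$construction) > -1e-9))
    expect_true(all(tr[, names(landClasses())] > -1e-12))
  }
  # high >= medium >= low construction at every year
  expect_true(all(trajs$high$construction >= trajs$medium$construction))
  expect_true(all(trajs$medium$construction >= trajs$low$construction))
  # strict ordering at the horizon
  expect_gt(demandAt(trajs$high, 2035)[["construction"]],
            demandAt(trajs$low, 2035)[["construction"]])
  # default calibration hits the low-scenario target
  expect_equal(demandAt(trajs$low, 2035)[["construction"]], 191.58,
               tolerance = 1e-8)

  # zero rates with zero intrinsic rates: fixed point
  fp <- runScenario(p, ScenarioSpec("still", 0, 0), 2025)
  for (nm in names(landClasses()))
    expect_equal(fp[[nm]], rep(p@areas0[[nm]], nrow(fp)))
})

test_that("relative error follows the printed-table convention", {
  expect_equal(round(relativeError(588358, 584438), 2), 0.67)
  expect_equal(round(relativeError(929.56, 932.13), 2), 0.28)
  expect_equal(relativeError(42, 42), 0)
  expect_error(relativeError(0, 5), "zero")
})

test_that("history validation passes on self-consistent data and flags perturbations", {
  p <- SDParams()
  sc <- ScenarioSpec("hist", 0.09, 0.003)
  h <- suppressWarnings(generateSDHistory(p, sc, nYears = 8, noiseSd = 0))
  traj <- suppressWarnings(runScenario(p, sc, p@baseYear + 7L))
  v <- validateHistory(traj, h)
  expect_true(v$pass)
  expect_true(all(v$table$rel_error_pct == 0))
  # 5 percent perturbation of one simulated value trips the flag
  h2 <- h
  h2$forest[3] <- h2$forest[3] / 1.05
  v2 <- validateHistory(traj, h2)
  expect_false(v2$pass)
  bad <- v2$table[v2$table$indicator == "forest" & v2$table$year == h$year[3], ]
  expect_equal(bad$rel_error_pct, 5, tolerance = 0.01)
  # disjoint years are rejected
  h3 <- h; h3$year <- h3$year + 100
  expect_error(validateHistory(traj, h3), "overlapping")
})

test_that("demand-equation coefficients are recovered from noise-free series", {
  p <- SDParams()
  h <- suppressWarnings(generateSDHistory(p, ScenarioSpec("hist", 0.09, 0.003),
                                          nYears = 20, noiseSd = 0))
  f <- fitSDCoefficients(h)
  expect_equal(f$urpopCoeff, -3.35e-5, tolerance = 1e-9)
  expect_equal(f$investCoeff, 5.727e-6, tolerance = 1e-9)
  expect_length(f$unidentifiable, 0)
})

test_that("a constant urban-population series leaves only the investment slope identifiable", {
  invest <- seq(1e6, 2e6, length.out = 10)
  h <- data.frame(construction = 150 + 5.727e-6 * invest,
                  urban_population = rep(2e5, 10), investment = invest)
  expect_warning(f <- fitSDCoefficients(h), "not identifiable")
  expect_true(is.na(f$urpopCoeff))
  expect_equal(f$investCoeff, 5.727e-6, tolerance = 1e-9)
  expect_identical(f$unidentifiable, "urpopCoeff")
})
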
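test_that("the regional equivalent follows yield x price / divisor", {
  expect_equal(regionalEquivalent(7000, 2.0, 7), 2000)
  expect_equal(regionalEquivalent(0, 2.44), 0)
  # regional inputs reproduce the published figure to within 0.01 percent
  eq <- regionalEquivalent(5968.322, 2.44, 7)
  expect_equal(eq, 2080.386, tolerance = 1e-6)
  expect_lt(abs(eq - 2080.356) / 2080.356, 1e-4)
  expect_error(regionalEquivalent(5000, 2, 0), "divisor")
})

test_that("the coefficient table loads with a passing column audit", {
  vc <- esvCoefficients()
  expect_identical(dim(vc), c(9L, 7L))
  expect_true(all(vc[, "construction"] == 0))
  expect_equal(attr(vc, "total")[["forest"]], 46620.78)
  # a corrupted table fails the audit naming the column
  df <- read.csv(system.file("extdata", "esv_coefficients.csv",
                             package = "landplus"), check.names = FALSE)
  df$forest[1] <- df$forest[1] + 5
  tmp <- tempfile(fileext = ".csv")
  write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  expect_error(esvCoefficients(tmp), "forest")
})

test_that("valuation is linear and its marginals are consistent", {
  areas <- landDemand2035("low")
  r <- esvMatrix(areas)
  expect_equal(sum(attr(r, "by_service")), attr(r, "total"))
  expect_equal(sum(attr(r, "by_land_type")), attr(r, "total"))
  expect_equal(attr(r, "total"), esvTotal(areas))
  r2 <- esvMatrix(areas * 2)
  expect_equal(as.numeric(r2), as.numeric(r) * 2)
  expect_equal(attr(r2, "total"), attr(r, "total") * 2)
  # all-construction landscape is worthless under the table
  expect_equal(esvTotal(c(construction = 500)), 0)
  expect_error(esvTotal(c(swamp = 10)), "swamp")
})

test_that("change analysis reports deltas, percents and zero-baseline guards", {
  a <- esvMatrix(landDemand2035("low"))
  chg0 <- esvChange(a, a)
  expect_true(all(chg0$delta == 0))
  expect_equal(chg0$total_pct, 0)
  b <- esvMatrix(landDemand2035("low") * 0.9)
  chg <- esvChange(a, b)
  expect_equal(chg$total_pct, -10, tolerance = 1e-9)
  # construction entries have zero baseline: percent change undefined
  expect_true(all(is.na(chg$pct[, "construction"])))
})

test_that("zonal values add up to the whole-map value", {
  cfg <- SynthConfig(nZones = 10, seed = 12)
  scene <- generateLandscapePair(cfg)
  z <- zonalESV(scene@luT1, scene@zones)
  expect_equal(nrow(z), 10L)
  expect_lt(abs(sum(z$esv_yuan) - esvTotal(areasFromRaster(scene@luT1))), 1)
  # single all-covering zone equals the map total
  one <- ZonePartition(matrix(1L, 50, 50), gridSpec(scene@luT1))
  # two-zone symmetric split of a uniform map gives equal halves
  lu <- LandUseRaster(matrix(3L, 10, 10))
  half <- ZonePartition(matrix(rep(c(1L, 2L), each = 50), 10, 10))
  zz <- zonalESV(lu, half)
  expect_equal(zz$esv_yuan[1], zz$esv_yuan[2])
  expect_equal(sum(zz$esv_yuan), esvTotal(areasFromRaster(lu)))
})

test_that("display rounding is half-up at two decimals in 1e8 yuan", {
  expect_equal(esvDisplay(21.965e8), 21.97)
  expect_equal(esvDisplay(-3.645e8), -3.65)
  expect_equal(esvDisplay(70.014e8), 70.01)
})
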
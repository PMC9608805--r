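test_that("scenario diversity flags exactly the disagreeing cells", {
  a <- LandUseRaster(matrix(1L, 6, 6))
  b <- LandUseRaster(matrix(1L, 6, 6))
  expect_true(all(scenarioDiversity(list(a, b)) == 0))
  c3 <- LandUseRaster(matrix(1L, 6, 6))
  c3@data[c(1, 5, 9, 14, 22, 30, 36)] <- 6L
  d <- scenarioDiversity(list(a, b, c3))
  expect_equal(sum(d), 7)
  # permutation symmetry
  expect_identical(d, scenarioDiversity(list(c3, b, a)))
  expect_error(scenarioDiversity(list(a)), "two")
  # nodata propagates
  bNA <- b; bNA@data[2] <- 0L
  expect_true(is.na(scenarioDiversity(list(a, bNA))[2]))
})

test_that("zonal sums respect partition additivity", {
  z <- blockZones(2, 2)  # 4 zones on a 4x4 grid
  r <- matrix(0, 4, 4)
  r[3:4, 1:2] <- 1       # 4 diversity cells in zone 3 (lower-left block)
  zs <- zonalSum(r, z)
  ca <- cellAreaKm2(gridSpec(z))
  expect_equal(zs$value_km2[zs$zone_id == 3], 4 * ca)
  expect_equal(sum(zs$value_km2), sum(r) * ca)
})

test_that("contiguity weights count rook and queen neighbours correctly", {
  z <- blockZones(2, 2)  # 2x2 layout of square zones
  rook <- contiguityWeights(z, "rook", rowStandardize = FALSE)
  expect_equal(unname(rowSums(rook@w)), rep(2, 4))
  queen <- contiguityWeights(z, "queen", rowStandardize = FALSE)
  expect_equal(unname(rowSums(queen@w)), rep(3, 4))
  std <- contiguityWeights(z, "queen")
  expect_equal(unname(rowSums(std@w)), rep(1, 4))
})

test_that("Moran's I hits its closed forms and the brute-force oracle", {
  # even checkerboard of block zones under row-standardized rook: I = -1
  z <- blockZones(4, 2)
  w <- contiguityWeights(z, "rook")
  vals <- as.vector(t(outer(1:4, 1:4, function(i, j) (-1)^(i + j))))
  m <- globalMoransI(vals, w, nPerm = 0)
  expect_equal(m$I, -1, tolerance = 1e-12)
  expect_equal(m$expected_I, -1 / 15)
  # arbitrary 6-zone fixture equals the double-loop oracle to 1e-12
  set.seed(9)
  z6 <- generateZones(GridSpec(12, 12), 6, seed = 2)
  w6 <- contiguityWeights(z6, "queen")
  v6 <- rnorm(6)
  m6 <- globalMoransI(v6, w6, nPerm = 99, seed = 1)
  expect_equal(m6$I, moranBruteForce(v6, w6), tolerance = 1e-12)
  # affine invariance
  m6b <- globalMoransI(5 * v6 - 3, w6, nPerm = 0)
  expect_equal(m6b$I, m6$I, tolerance = 1e-12)
  expect_error(globalMoransI(rep(1, 6), w6), "variance")
})

test_that("Gi* matches its brute-force oracle and orders a planted hot spot", {
  set.seed(4)
  z6 <- generateZones(GridSpec(12, 12), 6, seed = 2)
  w6 <- contiguityWeights(z6, "queen")
  v6 <- rnorm(6)
  gi <- getisOrdGiStar(v6, w6)
  expect_equal(gi$gi_z, giStarBruteForce(v6, w6), tolerance = 1e-12)
  # single high-value zone among equals has the top z-score
  v <- c(0, 0, 0, 10, 0, 0)
  gi2 <- getisOrdGiStar(v, w6)
  expect_equal(which.max(gi2$gi_z), 4L)
  expect_error(getisOrdGiStar(rep(2, 6), w6), "variance")
  # z-scores sum to ~0 under symmetric equal-degree weights
  wr <- ringWeights(12)
  set.seed(5)
  vr <- rnorm(12)
  gr <- getisOrdGiStar(vr, wr)
  expect_lt(abs(sum(gr$gi_z)), 1e-6 * 12)
})

test_that("the permutation test is close to nominal size under independence", {
  w <- contiguityWeights(blockZones(4, 2), "queen")
  reject <- logical(200)
  for (i in 1:200) {
    set.seed(3000 + i)
    v <- rnorm(16)
    reject[i] <- globalMoransI(v, w, nPerm = 999,
                               seed = 500 + i)$p_perm <= 0.05
  }
  expect_gte(mean(reject), 0.02)
  expect_lte(mean(reject), 0.09)
})
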
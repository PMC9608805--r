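# Small programmatic fixtures shared across test files.

# zone partition of an (nb x nb) block grid: each zone is one b x b block
blockZones <- function(nb = 4L, b = 2L) {
  ids <- matrix(0L, nb * b, nb * b)
  z <- 0L
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    z <- z + 1L
    ids[(i - 1L) * b + seq_len(b), (j - 1L) * b + seq_len(b)] <- z
  }
  ZonePartition(ids)
}

# ring adjacency weights (each zone two neighbours), symmetric after
# row-standardization because every degree is equal
ringWeights <- function(n, rowStandardize = TRUE) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w[i, i %% n + 1L] <- 1
    w[i %% n + 1L, i] <- 1
  }
  if (rowStandardize) w <- w / rowSums(w)
  new("SpatialWeights", ids = seq_len(n), w = w, scheme = "rook",
      rowStandardized = rowStandardize)
}

# brute-force double-loop Moran's I (independent oracle)
moranBruteForce <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  W <- w@w
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# brute-force Gi* z-scores (independent oracle, self-included weights)
giStarBruteForce <- function(values, w) {
  n <- length(values)
  W <- w@w
  diag(W) <- 1
  xbar <- mean(values)
  s <- sqrt(mean(values^2) - xbar^2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    wi <- sum(W[i, ]); wi2 <- sum(W[i, ]^2)
    num <- sum(W[i, ] * values) - xbar * wi
    out[i] <- num / (s * sqrt((n * wi2 - wi^2) / (n - 1)))
  }
  out
}

# a small PotentialSurfaces object with given per-class matrices
makePotentials <- function(surfaces, grid) {
  contribs <- lapply(surfaces, function(x) c(driver1 = 1))
  new("PotentialSurfaces", grid = grid, surfaces = surfaces,
      contributions = contribs)
}

# printed relative-error rows of the demand-model validation table
# (indicator blocks in file order: population, construction, cultivated,
# forest; years 2011..2018)
printedValidationErrors <- c(
  0.49, 0.67, 0.77, 0.14, 0.22, 0.03, 0.07, 0.26,
  1.33, 0.13, 0.80, 0.37, 0.90, 0.78, 0.47, 0.19,
  0.29, 0.04, 0.17, 0.24, 0.44, 0.30, 0.38, 0.57,
  0.37, 0.28, 0.13, 0.16, 0.19, 0.23, 0.12, 0.44)
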
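## Scenario-diversity mapping and spatial autocorrelation.
##
## The diversity raster flags cells where simulated scenarios disagree;
## per-zone diversity areas feed global Moran's I (permutation-tested) and
## Getis-Ord Gi* hot/cold classification under contiguity weights derived
## from the rasterized zone adjacency.

#' Cross-scenario disagreement raster
#'
#' Cell value 1 where not all maps agree on the class, 0 where they all
#' agree; nodata (in any map) propagates as NA.
#'
#' @param maps list of >= 2 \linkS4class{LandUseRaster}s on a shared grid.
#' @return Numeric matrix of 0/1 (NA = nodata).
#' @export
scenarioDiversity <- function(maps) {
  if (length(maps) < 2L) stop("need at least two scenario maps")
  g <- maps[[1]]@grid
  for (m in maps[-1]) stopifnot(sameGrid(g, m@grid))
  stack <- lapply(maps, rasterData)
  nodata <- Reduce(`|`, lapply(stack, function(d) d == NODATA_CODE))
  agree <- Reduce(`&`, lapply(stack[-1], function(d) d == stack[[1]]))
  out <- ifelse(agree, 0, 1)
  out[nodata] <- NA_real_
  out
}

#' Per-zone sum of a numeric raster, in km2
#'
#' @param raster numeric matrix (cell values; NAs ignored).
#' @param zones a \linkS4class{ZonePartition} of matching dimensions.
#' @return data.frame \code{zone_id, value_km2}: per-zone sum times cell
#'   area.
#' @export
zonalSum <- function(raster, zones) {
  stopifnot(all(dim(raster) == dim(zones@zoneIds)))
  cellArea <- cellAreaKm2(zones@grid)
  zids <- zones@table$zone_id
  sums <- vapply(zids, function(z)
    sum(raster[zones@zoneIds == z], na.rm = TRUE) * cellArea, 0)
  data.frame(zone_id = zids, value_km2 = sums)
}

#' Contiguity spatial weights from a rasterized zone partition
#'
#' Two zones are rook neighbours when any two of their cells share an
#' edge, queen neighbours when they share an edge or a corner. Weights are
#' binary, optionally row-standardized (default). Island zones get a zero
#' row, with a message.
#'
#' @param zones a \linkS4class{ZonePartition} (>= 2 zones).
#' @param scheme "queen" (default) or "rook".
#' @param rowStandardize logical (default TRUE).
#' @return A \linkS4class{SpatialWeights}.
#' @export
contiguityWeights <- function(zones, scheme = c("queen", "rook"),
                              rowStandardize = TRUE) {
  scheme <- match.arg(scheme)
  z <- zones@zoneIds
  ids <- sort(unique(zones@table$zone_id))
  if (length(ids) < 2L) stop("need at least two zones")
  idx <- match(z, ids)
  dim(idx) <- dim(z)
  n <- length(ids)
  w <- matrix(0, n, n)
  pair <- function(a, b) {
    keep <- !is.na(a) & !is.na(b) & a != b
    if (any(keep)) {
      w[cbind(a[keep], b[keep])] <<- 1
      w[cbind(b[keep], a[keep])] <<- 1
    }
  }
  nr <- nrow(idx); nc <- ncol(idx)
  pair(idx[-nr, ], idx[-1, ])             # vertical edges
  pair(idx[, -nc], idx[, -1])             # horizontal edges
  if (scheme == "queen") {
    pair(idx[-nr, -nc], idx[-1, -1])      # diagonal \
    pair(idx[-nr, -1], idx[-1, -nc])      # diagonal /
  }
  if (any(rowSums(w) == 0))
    message("island zone(s) with no neighbours: ",
            paste(ids[rowSums(w) == 0], collapse = ", "))
  if (rowStandardize) {
    rs <- rowSums(w)
    w[rs > 0, ] <- w[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  new("SpatialWeights", ids = as.integer(ids), w = w, scheme = scheme,
      rowStandardized = rowStandardize)
}

#' Global Moran's I with a permutation test
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_i \sum_j w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with \eqn{z} the deviations from the mean and \eqn{S_0} the weight sum.
#' The expectation under no autocorrelation is \eqn{-1/(n-1)}. The pseudo
#' p-value is two-sided, from \code{nPerm} seeded random relabelings
#' (the observed arrangement counted among the permutations); an analytic
#' normal-approximation p-value is reported alongside.
#'
#' @param values per-zone numeric vector, in the order of \code{w@ids}.
#' @param w a \linkS4class{SpatialWeights}.
#' @param nPerm number of permutations (default 999; 0 disables).
#' @param seed RNG seed for the permutations.
#' @return List: \code{I}, \code{expected_I}, \code{p_perm},
#'   \code{p_normal}, \code{nPerm}.
#' @export
globalMoransI <- function(values, w, nPerm = 999L, seed = 1L) {
  n <- length(values)
  stopifnot(n == length(w@ids), n >= 3L)
  if (stats::sd(values) == 0)
    stop("Moran's I undefined for zero-variance values")
  W <- w@w
  S0 <- sum(W)
  z <- values - mean(values)
  denom <- sum(z^2)
  I <- (n / S0) * sum(z * (W %*% z)) / denom
  EI <- -1 / (n - 1)
  ## analytic variance under normality
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  varI <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - EI^2
  pNorm <- 2 * stats::pnorm(-abs((I - EI) / sqrt(varI)))
  pPerm <- NA_real_
  if (nPerm > 0L) {
    set.seed(seed)
    P <- vapply(seq_len(nPerm), function(i) sample(z), numeric(n))
    Iperm <- (n / S0) * colSums(P * (W %*% P)) / denom  # denom is permutation-invariant
    extreme <- sum(abs(Iperm - EI) >= abs(I - EI) - 1e-12)
    pPerm <- (extreme + 1) / (nPerm + 1)
  }
  list(I = I, expected_I = EI, p_perm = pPerm, p_normal = pNorm,
       nPerm = nPerm)
}

#' Getis-Ord Gi* hot/cold spot statistics
#'
#' Gi* with self-included weights:
#' \deqn{G_i^* = \frac{\sum_j w_{ij} x_j - \bar{x} \sum_j w_{ij}}
#'  {S \sqrt{(n \sum_j w_{ij}^2 - (\sum_j w_{ij})^2)/(n-1)}}}
#' Zones are labelled hot/cold at |z| thresholds 1.65 / 1.96 / 2.58
#' (90 / 95 / 99 percent confidence), else not significant.
#'
#' @param values per-zone numeric vector, in the order of \code{w@ids}.
#' @param w a \linkS4class{SpatialWeights}; a unit self-weight is added
#'   internally (Gi* includes the focal zone).
#' @return data.frame \code{zone_id, value, gi_z, gi_class} with class
#'   labels in \{cold-99, cold-95, cold-90, ns, hot-90, hot-95, hot-99\}.
#' @export
getisOrdGiStar <- function(values, w) {
  n <- length(values)
  stopifnot(n == length(w@ids), n >= 3L)
  if (stats::sd(values) == 0)
    stop("Gi* undefined for zero-variance values")
  Wstar <- w@w
  diag(Wstar) <- 1                          # self-included
  xbar <- mean(values)
  s <- sqrt(sum(values^2) / n - xbar^2)
  wi <- rowSums(Wstar)
  wi2 <- rowSums(Wstar^2)
  num <- as.numeric(Wstar %*% values) - xbar * wi
  den <- s * sqrt((n * wi2 - wi^2) / (n - 1))
  zscore <- num / den
  lab <- cut(zscore,
             breaks = c(-Inf, -2.58, -1.96, -1.65, 1.65, 1.96, 2.58, Inf),
             labels = c("cold-99", "cold-95", "cold-90", "ns",
                        "hot-90", "hot-95", "hot-99"))
  data.frame(zone_id = w@ids, value = values, gi_z = zscore,
             gi_class = as.character(lab))
}
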
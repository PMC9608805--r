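## Synthetic-landscape generator.
##
## Produces every input the pipeline needs with known ground truth: paired
## land-use rasters with exact class-transition counts placed along
## configurable driver gradients, spatially autocorrelated driver stacks,
## binary restriction masks that are guaranteed never to change, Voronoi
## zone tessellations standing in for village boundaries, and
## socio-economic histories generated from the demand model's own
## equations plus optional Gaussian noise.

## separable Gaussian smoothing with edge renormalization
.smoothMatrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], half), x, rep(x[n], half))  # replicate-pad edges
    as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

#' Generate a stack of spatially autocorrelated driver rasters
#'
#' Each layer is standard Gaussian noise convolved with a Gaussian kernel
#' of bandwidth \code{smoothness} (in cells); \code{smoothness = 0} yields
#' i.i.d. per-cell noise. Values are raw (not normalized).
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param nDrivers number of layers (>= 1).
#' @param smoothness Gaussian bandwidth in cells (>= 0).
#' @param seed RNG seed.
#' @return A \linkS4class{DriverStack} with layers named
#'   \code{driver1..driverN}.
#' @export
generateDrivers <- function(grid, nDrivers = 3L, smoothness = 3, seed = 1L) {
  validObject(grid)
  stopifnot(nDrivers >= 1L, smoothness >= 0)
  set.seed(seed)
  layers <- lapply(seq_len(nDrivers), function(i)
    .smoothMatrix(matrix(stats::rnorm(grid@nrows * grid@ncols),
                         grid@nrows, grid@ncols), smoothness))
  names(layers) <- paste0("driver", seq_len(nDrivers))
  DriverStack(layers, grid, normalized = FALSE)
}

#' Generate a Voronoi zone tessellation of the grid
#'
#' Samples \code{nZones} distinct cells as zone seeds and assigns every
#' cell to its nearest seed (Euclidean distance on cell centres, lowest id
#' on ties), giving contiguous irregular zones resembling village
#' boundaries.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param nZones number of zones (2 <= nZones <= number of cells).
#' @param seed RNG seed.
#' @return A \linkS4class{ZonePartition} with zone ids 1..nZones.
#' @export
generateZones <- function(grid, nZones, seed = 1L) {
  validObject(grid)
  ncell <- grid@nrows * grid@ncols
  if (nZones < 2L || nZones > ncell)
    stop("nZones must lie in [2, number of cells]")
  set.seed(seed)
  seeds <- sample.int(ncell, nZones)
  sr <- (seeds - 1L) %% grid@nrows + 1L
  sc <- (seeds - 1L) %/% grid@nrows + 1L
  rows <- matrix(seq_len(grid@nrows), grid@nrows, grid@ncols)
  cols <- matrix(rep(seq_len(grid@ncols), each = grid@nrows),
                 grid@nrows, grid@ncols)
  best <- matrix(Inf, grid@nrows, grid@ncols)
  ids <- matrix(0L, grid@nrows, grid@ncols)
  for (z in seq_len(nZones)) {
    d <- (rows - sr[z])^2 + (cols - sc[z])^2
    closer <- d < best
    ids[closer] <- z
    best[closer] <- d[closer]
  }
  ZonePartition(ids, grid)
}

#' Configuration for a synthetic landscape pair
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param classProportions 7 nonnegative fractions (package class order)
#'   summing to 1.
#' @param transitionCounts data.frame with columns from, to, count: the
#'   exact number of cells to convert per class pair.
#' @param driverEffect named numeric vector of linear effect sizes on the
#'   standardized drivers; transition cells are the top-ranked eligible
#'   cells under this score.
#' @param restrictionFraction fraction of cells masked against change.
#' @param nZones zones in the tessellation.
#' @param nDrivers,smoothness passed to \code{\link{generateDrivers}}.
#' @param seed master RNG seed.
#' @return A validated configuration list of class \code{SynthConfig}.
#' @export
SynthConfig <- function(grid = GridSpec(50, 50),
                        classProportions = c(cultivated = 0.26,
                                             grassland = 0.02,
                                             forest = 0.55, water = 0.05,
                                             garden = 0.02,
                                             construction = 0.08,
                                             other = 0.02),
                        transitionCounts = data.frame(
                          from = c(1L, 3L, 1L, 3L, 1L, 3L),
                          to   = c(6L, 6L, 5L, 5L, 7L, 7L),
                          count = c(40L, 20L, 15L, 10L, 6L, 5L)),
                        driverEffect = c(driver1 = 4, driver2 = 0.5,
                                         driver3 = 0.5),
                        restrictionFraction = 0.2, nZones = 12L,
                        nDrivers = 3L, smoothness = 3, seed = 1L) {
  stopifnot(length(classProportions) == 7L, all(classProportions >= 0),
            abs(sum(classProportions) - 1) < 1e-9,
            restrictionFraction >= 0, restrictionFraction < 1,
            all(c("from", "to", "count") %in% names(transitionCounts)))
  structure(list(grid = grid, classProportions = classProportions,
                 transitionCounts = transitionCounts,
                 driverEffect = driverEffect,
                 restrictionFraction = restrictionFraction,
                 nZones = as.integer(nZones), nDrivers = as.integer(nDrivers),
                 smoothness = smoothness, seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Generate a paired synthetic landscape with known transitions
#'
#' Builds a t0 land-use raster with the configured class proportions,
#' draws driver layers and a restriction mask, then converts, for each
#' configured (from, to) pair, exactly \code{count} cells of class
#' \code{from} to class \code{to}: the eligible (unrestricted, unconverted)
#' cells with the highest linear driver score, ties broken by seeded
#' random keys. Restricted cells never change; the realized transition
#' cross-tabulation equals the configuration exactly.
#'
#' @param config a \code{\link{SynthConfig}}.
#' @return A \linkS4class{SyntheticScene}.
#' @export
generateLandscapePair <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  grid <- config$grid
  ncell <- grid@nrows * grid@ncols
  drivers <- generateDrivers(grid, config$nDrivers, config$smoothness,
                             seed = config$seed + 1L)
  zones <- generateZones(grid, config$nZones, seed = config$seed + 2L)
  set.seed(config$seed)
  ## class layout: exact cell counts by largest remainder
  target <- config$classProportions * ncell
  counts <- floor(target)
  short <- ncell - sum(counts)
  if (short > 0) {
    extra <- order(target - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  codes <- rep(landClasses(), times = counts)
  lu0 <- matrix(sample(codes), grid@nrows, grid@ncols)
  restriction <- matrix(0L, grid@nrows, grid@ncols)
  nRestrict <- floor(config$restrictionFraction * ncell)
  if (nRestrict > 0)
    restriction[sample.int(ncell, nRestrict)] <- 1L
  ## linear driver score, standardized per layer
  eff <- config$driverEffect
  score <- matrix(0, grid@nrows, grid@ncols)
  for (nm in names(eff)) {
    lay <- drivers@layers[[nm]]
    if (is.null(lay)) stop("driverEffect names a missing layer: ", nm)
    score <- score + eff[[nm]] * (lay - mean(lay)) / stats::sd(lay)
  }
  tieKey <- stats::runif(ncell)
  lu1 <- lu0
  converted <- matrix(FALSE, grid@nrows, grid@ncols)
  tc <- config$transitionCounts
  for (i in seq_len(nrow(tc))) {
    from <- tc$from[i]; to <- tc$to[i]; count <- tc$count[i]
    if (count == 0) next
    eligible <- which(lu0 == from & restriction == 0L & !converted)
    if (length(eligible) < count)
      stop(sprintf("transition %d->%d demands %d cells but only %d eligible",
                   from, to, count, length(eligible)))
    ranked <- eligible[order(score[eligible], tieKey[eligible],
                             decreasing = TRUE)]
    pick <- ranked[seq_len(count)]
    lu1[pick] <- as.integer(to)
    converted[pick] <- TRUE
  }
  new("SyntheticScene",
      luT0 = LandUseRaster(lu0, grid), luT1 = LandUseRaster(lu1, grid),
      drivers = drivers, restriction = restriction, zones = zones,
      truth = unclass(config))
}

#' Cross-tabulation of class transitions between two rasters
#' @param luT0,luT1 \linkS4class{LandUseRaster} pair on a shared grid.
#' @return 7x7 integer matrix of cell counts (rows = from, cols = to).
#' @export
transitionTable <- function(luT0, luT1) {
  stopifnot(sameGrid(luT0@grid, luT1@grid))
  ok <- luT0@data != NODATA_CODE & luT1@data != NODATA_CODE
  table(factor(luT0@data[ok], levels = 1:7),
        factor(luT1@data[ok], levels = 1:7))
}

#' Generate a socio-economic history from the demand model
#'
#' Runs the demand model forward \code{nYears} from the base state under
#' the given scenario rates and adds independent Gaussian noise per
#' series. With \code{noiseSd = 0} the result equals the deterministic
#' \code{\link{runScenario}} trajectory exactly.
#'
#' @param params an \linkS4class{SDParams}.
#' @param scenario a \linkS4class{ScenarioSpec} (default: the medium
#'   scenario rates).
#' @param nYears number of years in the series (>= 2).
#' @param noiseSd scalar, or named vector over series columns, of Gaussian
#'   noise standard deviations (>= 0).
#' @param seed RNG seed for the noise.
#' @return data.frame with columns year, total_population,
#'   urban_population, gdp, investment and the seven class areas.
#' @export
generateSDHistory <- function(params, scenario = ScenarioSpec("medium", 0.104, 0.0035),
                              nYears = 8L, noiseSd = 0, seed = 1L) {
  stopifnot(nYears >= 2L)
  if (any(noiseSd < 0)) stop("noiseSd must be nonnegative")
  traj <- runScenario(params, scenario, params@baseYear + nYears - 1L)
  hist <- as.data.frame(traj)
  attr(hist, "scenario") <- NULL
  class(hist) <- "data.frame"
  series <- setdiff(names(hist), "year")
  sd <- if (length(noiseSd) == 1L)
    stats::setNames(rep(noiseSd, length(series)), series)
  else {
    out <- stats::setNames(rep(0, length(series)), series)
    out[names(noiseSd)] <- noiseSd
    out
  }
  set.seed(seed)
  for (nm in series)
    if (sd[nm] > 0)
      hist[[nm]] <- pmax(0, hist[[nm]] + stats::rnorm(nrow(hist), 0, sd[nm]))
  hist
}
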
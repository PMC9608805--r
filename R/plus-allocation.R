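## Patch-generating CA allocation.
##
## Stage 1 (expansion analysis): cells that converted to a class between
## two dated maps are positive examples; a random-forest classifier on the
## normalized driver stack yields a development-potential surface per
## class plus normalized per-driver contribution scores.
## Stage 2 (allocation): demands are met by iterative conversion. Cells
## adjacent to existing patches of a class compete by potential x
## neighbourhood density; where the neighbourhood effect is zero, new
## patch seeds fire by a Monte-Carlo draw against a per-class threshold
## that decays multiplicatively every sweep the class's demand stays
## unmet. Restriction masks and a transition-legality matrix are enforced
## throughout.

#' Min-max normalize a driver stack
#'
#' Rescales each layer to [0, 1]; already-normalized stacks are returned
#' unchanged (idempotent).
#'
#' @param stack a \linkS4class{DriverStack}.
#' @return The normalized \linkS4class{DriverStack}.
#' @export
normalizeDrivers <- function(stack) {
  if (isTRUE(stack@normalized)) return(stack)
  layers <- lapply(names(stack@layers), function(nm) {
    m <- stack@layers[[nm]]
    rng <- range(m, na.rm = TRUE)
    if (diff(rng) == 0)
      stop("driver layer '", nm, "' is constant and cannot be normalized")
    (m - rng[1]) / diff(rng)
  })
  names(layers) <- names(stack@layers)
  DriverStack(layers, stack@grid, normalized = TRUE)
}

#' Extract expansion samples from a dated raster pair
#'
#' For each land class k, positive samples are cells newly converted to k
#' between t0 and t1; negative samples are drawn uniformly from unchanged
#' cells, one per positive (balanced classes). \code{sampleRate} thins the
#' positives (floor of rate x available, at least 1).
#'
#' @param luT0,luT1 \linkS4class{LandUseRaster} pair on a shared grid.
#' @param sampleRate fraction of available cells to sample (0, 1].
#' @param seed RNG seed.
#' @return A \code{SampleSet}: per-class list of data.frames with columns
#'   \code{cell} (linear index) and \code{label} (1 = expanded to class).
#' @export
extractExpansionSamples <- function(luT0, luT1, sampleRate = 1, seed = 1L) {
  stopifnot(sameGrid(luT0@grid, luT1@grid),
            sampleRate > 0, sampleRate <= 1)
  a <- luT0@data; b <- luT1@data
  valid <- a != NODATA_CODE & b != NODATA_CODE
  changed <- which(valid & a != b)
  if (!length(changed))
    stop("the two rasters are identical; nothing to learn from")
  unchanged <- which(valid & a == b)
  set.seed(seed)
  classes <- sort(unique(b[changed]))
  out <- lapply(classes, function(k) {
    pos <- changed[b[changed] == k]
    nPos <- max(1L, floor(sampleRate * length(pos)))
    if (nPos < length(pos)) pos <- sample(pos, nPos)
    neg <- sample(unchanged, min(length(pos), length(unchanged)))
    data.frame(cell = c(pos, neg),
               label = rep(c(1L, 0L), c(length(pos), length(neg))))
  })
  structure(stats::setNames(out, classes), class = "SampleSet")
}

#' Fit per-class expansion models and predict potential surfaces
#'
#' Trains one binary random forest per class (one-vs-rest) on the driver
#' values at the sampled cells and predicts the expansion probability at
#' every cell, together with normalized per-driver importance scores.
#' Classes with fewer than 2 positives or 2 negatives receive a flat
#' surface at the sample prevalence and NA contributions, with a warning.
#'
#' @param samples a \code{SampleSet} from
#'   \code{\link{extractExpansionSamples}}.
#' @param drivers a normalized \linkS4class{DriverStack}.
#' @param nTrees trees per forest (default 100).
#' @param seed RNG seed for the forests.
#' @param classes class codes to produce surfaces for (default: the
#'   classes present in \code{samples}); classes without samples get a
#'   flat 0.5 surface (uninformative suitability) with a warning.
#' @return A \linkS4class{PotentialSurfaces}.
#' @export
fitExpansionModel <- function(samples, drivers, nTrees = 100L, seed = 1L,
                              classes = names(samples)) {
  stopifnot(inherits(samples, "SampleSet"))
  if (!isTRUE(drivers@normalized))
    stop("drivers must be normalized first (see normalizeDrivers)")
  grid <- drivers@grid
  X <- do.call(cbind, lapply(drivers@layers, as.vector))
  colnames(X) <- names(drivers@layers)
  allDf <- as.data.frame(X)
  surfaces <- list(); contribs <- list()
  for (k in as.character(classes)) {
    s <- samples[[k]]
    if (is.null(s)) {
      warning("class ", k, " has no expansion samples; using a flat surface",
              call. = FALSE)
      surfaces[[k]] <- matrix(0.5, grid@nrows, grid@ncols)
      contribs[[k]] <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
      next
    }
    nPos <- sum(s$label == 1L); nNeg <- sum(s$label == 0L)
    if (nPos < 2L || nNeg < 2L) {
      warning("class ", k, " has too few samples; using a flat surface",
              call. = FALSE)
      prev <- nPos / max(1L, nrow(s))
      surfaces[[k]] <- matrix(prev, grid@nrows, grid@ncols)
      contribs[[k]] <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
      next
    }
    df <- data.frame(y = factor(s$label, levels = c(0L, 1L)),
                     allDf[s$cell, , drop = FALSE])
    fit <- ranger::ranger(y ~ ., data = df, num.trees = nTrees,
                          probability = TRUE, importance = "impurity",
                          seed = seed, num.threads = 1L)
    p <- stats::predict(fit, allDf, num.threads = 1L)$predictions[, "1"]
    surfaces[[k]] <- matrix(p, grid@nrows, grid@ncols)
    imp <- fit$variable.importance
    imp <- pmax(imp, 0)
    contribs[[k]] <- if (sum(imp) > 0) imp / sum(imp)
                     else stats::setNames(rep(1 / length(imp), length(imp)),
                                          names(imp))
  }
  new("PotentialSurfaces", grid = grid, surfaces = surfaces,
      contributions = contribs)
}

## truncated-window box sum via summed-area tables
.boxSum <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(m, 2, cumsum)
  top <- rbind(matrix(0, 1, nc), cs)
  rows <- cs[pmin(seq_len(nr) + h, nr), , drop = FALSE] -
    top[pmax(seq_len(nr) - h - 1L, 0L) + 1L, , drop = FALSE]
  cs2 <- t(apply(rows, 1, cumsum))
  left <- cbind(matrix(0, nr, 1), cs2)
  cs2[, pmin(seq_len(nc) + h, nc), drop = FALSE] -
    left[, pmax(seq_len(nc) - h - 1L, 0L) + 1L, drop = FALSE]
}

#' Neighbourhood effect of a land class
#'
#' Per cell, the fraction of cells in the centred window (truncated at the
#' raster edge, nodata excluded from the denominator, centre included)
#' currently carrying class \code{k}.
#'
#' @param lu a \linkS4class{LandUseRaster}.
#' @param k class code (1..7).
#' @param window odd window side length >= 3 (default 3, the Moore
#'   neighbourhood).
#' @return Numeric matrix in [0, 1].
#' @export
neighborhoodEffect <- function(lu, k, window = 3L) {
  if (window %% 2L != 1L || window < 3L)
    stop("window must be an odd integer >= 3")
  h <- (window - 1L) %/% 2L
  isK <- (lu@data == k) * 1
  isValid <- (lu@data != NODATA_CODE) * 1
  num <- .boxSum(isK, h)
  den <- .boxSum(isValid, h)
  out <- ifelse(den > 0, num / den, 0)
  out[lu@data == NODATA_CODE] <- 0
  out
}

#' Configuration of the CA allocation stage
#'
#' @param transitionMatrix 7x7 logical matrix of allowed from-to
#'   conversions (diagonal must be TRUE); default: everything allowed.
#' @param neighborhoodWindow odd window side (default 3).
#' @param neighborhoodWeights named per-class weights of the neighbourhood
#'   term; a weight of 0 disables patch growth for that class so all its
#'   conversions come from seeding.
#' @param decayFactor multiplicative threshold decay in (0, 1] per sweep a
#'   class's demand stays unmet (default 0.9).
#' @param initialThreshold starting seed threshold (default 1; 0 disables
#'   the Monte-Carlo gate entirely, making allocation deterministic
#'   ranking by potential).
#' @param demandTolerance tolerated demand miss in km2 (default 0; one
#'   cell is always tolerated).
#' @param maxIterations sweep cap (default 1000).
#' @param seed RNG seed of the run.
#' @return A validated configuration list of class \code{CarsConfig}.
#' @export
CarsConfig <- function(transitionMatrix = matrix(TRUE, 7, 7),
                       neighborhoodWindow = 3L,
                       neighborhoodWeights = stats::setNames(rep(1, 7),
                                                             names(landClasses())),
                       decayFactor = 0.9, initialThreshold = 1,
                       demandTolerance = 0, maxIterations = 1000L,
                       seed = 1L) {
  stopifnot(is.matrix(transitionMatrix), all(dim(transitionMatrix) == 7L),
            all(diag(transitionMatrix)),
            neighborhoodWindow %% 2L == 1L,
            decayFactor > 0, decayFactor <= 1,
            initialThreshold >= 0, demandTolerance >= 0, maxIterations >= 1L)
  structure(list(transitionMatrix = transitionMatrix,
                 neighborhoodWindow = as.integer(neighborhoodWindow),
                 neighborhoodWeights = neighborhoodWeights,
                 decayFactor = decayFactor,
                 initialThreshold = initialThreshold,
                 demandTolerance = demandTolerance,
                 maxIterations = as.integer(maxIterations),
                 seed = as.integer(seed)),
            class = "CarsConfig")
}

#' Allocate per-class demands on the map by patch-generating CA
#'
#' Iteratively converts cells until every class's cell demand is met.
#' Within a sweep each expanding class scores candidate cells (donor class
#' has surplus, conversion legal, cell unrestricted): cells touching an
#' existing patch score potential x weighted neighbourhood density; cells
#' with zero neighbourhood effect can only enter as Monte-Carlo seeds,
#' accepted when \code{P >= threshold * u} with u uniform. Candidates are
#' taken highest score first (random tie-break under the run seed) while
#' demand and donor supply last. After each sweep the threshold of every
#' unmet class decays by \code{decayFactor}.
#'
#' @param luT0 starting \linkS4class{LandUseRaster}.
#' @param potentials \linkS4class{PotentialSurfaces} on the same grid.
#' @param demand named per-class target areas in km2 (all seven classes);
#'   must total the map's non-nodata area within tolerance.
#' @param restriction integer matrix, 1 = cell may not change (NULL = no
#'   restriction).
#' @param cfg a \code{\link{CarsConfig}}.
#' @return The final \linkS4class{LandUseRaster}; attribute \code{"unmet"}
#'   carries any per-class residual cell demand when the iteration cap was
#'   hit (with a warning), and attribute \code{"sweeps"} the sweep count.
#' @export
carsSimulate <- function(luT0, potentials, demand, restriction = NULL,
                         cfg = CarsConfig()) {
  stopifnot(inherits(cfg, "CarsConfig"),
            sameGrid(luT0@grid, potentials@grid))
  grid <- luT0@grid
  cellArea <- cellAreaKm2(grid)
  if (is.null(restriction))
    restriction <- matrix(0L, grid@nrows, grid@ncols)
  demand <- demand[names(landClasses())]
  valid <- luT0@data != NODATA_CODE
  totalCells <- sum(valid)
  exact <- demand / cellArea
  targetCells <- floor(exact + 0.5)
  tolCells <- max(1, floor(cfg$demandTolerance / cellArea + 0.5))
  if (abs(sum(targetCells) - totalCells) > max(tolCells * 7, 7))
    stop("demand total (", sum(targetCells), " cells) does not match the map (",
         totalCells, " cells)")
  ## reconcile per-class rounding so the targets partition the map exactly
  gap <- totalCells - sum(targetCells)
  while (gap != 0L) {
    resid <- exact - targetCells
    j <- if (gap > 0L) which.max(resid) else which.min(resid)
    targetCells[j] <- targetCells[j] + sign(gap)
    gap <- gap - sign(gap)
  }
  ## restricted cells keep their class, so no target may fall below a
  ## class's restricted count; the excess is debited from slack classes
  restrCounts <- tabulate(luT0@data[valid & restriction == 1L], nbins = 7L)
  shortfall <- pmax(restrCounts - targetCells, 0L)
  if (sum(shortfall) > 0L) {
    targetCells <- targetCells + shortfall
    excess <- sum(shortfall)
    while (excess > 0L) {
      j <- which.max(targetCells - restrCounts)
      if (targetCells[j] <= restrCounts[j])
        stop("restriction mask leaves no feasible demand partition")
      targetCells[j] <- targetCells[j] - 1L
      excess <- excess - 1L
    }
  }
  cur <- luT0@data
  counts <- tabulate(cur[valid], nbins = 7L)
  deficit <- as.integer(targetCells) - counts      # + needs growth
  expanding <- which(deficit > 0)
  noSurface <- setdiff(as.character(expanding), names(potentials@surfaces))
  if (length(noSurface))
    stop("no potential surface for expanding class(es): ",
         paste(noSurface, collapse = ", "))
  ## feasibility: every expanding class needs some legal donor
  for (k in expanding) {
    donors <- which(cfg$transitionMatrix[, k] & seq_len(7) != k)
    if (!any(counts[donors] > targetCells[donors]))
      stop("demand for class ", k,
           " infeasible under the transition matrix")
  }
  set.seed(cfg$seed)
  thr <- stats::setNames(rep(cfg$initialThreshold, 7), 1:7)
  wts <- cfg$neighborhoodWeights[names(landClasses())]
  names(wts) <- 1:7
  sweeps <- 0L
  while (any(deficit > tolCells - 1L & deficit > 0L) &&
         sweeps < cfg$maxIterations) {
    sweeps <- sweeps + 1L
    luNow <- LandUseRaster(cur, grid)
    candCell <- integer(); candClass <- integer(); candScore <- numeric()
    for (k in which(deficit > 0L)) {
      P <- potentials@surfaces[[as.character(k)]]
      legalFrom <- cfg$transitionMatrix[, k]
      donorOk <- counts > targetCells          # classes with surplus
      eligible <- valid & restriction == 0L & cur != k &
        matrix(legalFrom[cur] & donorOk[cur], grid@nrows, grid@ncols)
      if (!any(eligible)) next
      w <- wts[[as.character(k)]]
      if (w > 0) {
        Nk <- neighborhoodEffect(luNow, k, cfg$neighborhoodWindow)
      } else {
        Nk <- matrix(0, grid@nrows, grid@ncols)
      }
      growth <- eligible & Nk > 0 & w > 0
      seedZone <- eligible & !(Nk > 0 & w > 0)
      idxG <- which(growth)
      if (length(idxG)) {
        candCell <- c(candCell, idxG)
        candClass <- c(candClass, rep(k, length(idxG)))
        candScore <- c(candScore, P[idxG] * w * Nk[idxG])
      }
      idxS <- which(seedZone)
      if (length(idxS)) {
        if (cfg$initialThreshold > 0) {
          u <- stats::runif(length(idxS))
          keep <- P[idxS] >= thr[[as.character(k)]] * u
          idxS <- idxS[keep]
        }
        if (length(idxS)) {
          candCell <- c(candCell, idxS)
          candClass <- c(candClass, rep(k, length(idxS)))
          candScore <- c(candScore, P[idxS])
        }
      }
    }
    if (length(candCell)) {
      ord <- order(candScore, stats::runif(length(candScore)),
                   decreasing = TRUE)
      takenThisSweep <- logical(length(cur))
      for (j in ord) {
        k <- candClass[j]; cell <- candCell[j]
        if (deficit[k] <= 0L || takenThisSweep[cell]) next
        from <- cur[cell]
        if (counts[from] <= targetCells[from]) next  # donor supply gone
        cur[cell] <- as.integer(k)
        takenThisSweep[cell] <- TRUE
        counts[from] <- counts[from] - 1L
        counts[k] <- counts[k] + 1L
        deficit[k] <- deficit[k] - 1L
        deficit[from] <- deficit[from] + 1L
      }
    }
    unmet <- deficit > 0L
    thr[unmet] <- thr[unmet] * cfg$decayFactor
  }
  out <- LandUseRaster(cur, grid)
  if (any(deficit > 0L)) {
    res <- stats::setNames(pmax(deficit, 0L), names(landClasses()))
    if (any(res > tolCells)) {
      warning("iteration cap reached with unmet demand (cells): ",
              paste(sprintf("%s=%d", names(res)[res > 0], res[res > 0]),
                    collapse = " "), call. = FALSE)
      attr(out, "unmet") <- res
    }
  }
  attr(out, "sweeps") <- sweeps
  out
}

#' Cell-by-cell agreement of two categorical maps
#'
#' Overall accuracy (agreeing / valid cells) and Cohen's kappa from the
#' 7x7 confusion matrix; cells that are nodata in either map are excluded.
#' Degenerate marginals (a constant map, \code{p_e = 1}) yield kappa 0 by
#' convention, with a message.
#'
#' @param sim simulated \linkS4class{LandUseRaster}.
#' @param actual reference \linkS4class{LandUseRaster}.
#' @return List with \code{overall_accuracy}, \code{kappa} and
#'   \code{confusion} (7x7 counts, rows = actual, cols = simulated).
#' @export
validateMap <- function(sim, actual) {
  stopifnot(sameGrid(sim@grid, actual@grid))
  ok <- sim@data != NODATA_CODE & actual@data != NODATA_CODE
  if (!any(ok)) stop("no overlapping valid cells")
  conf <- table(factor(actual@data[ok], levels = 1:7),
                factor(sim@data[ok], levels = 1:7))
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) {
    message("degenerate marginals (pe = 1); kappa set to 0 by convention")
    0
  } else (po - pe) / (1 - pe)
  list(overall_accuracy = po, kappa = kappa, confusion = unclass(conf))
}
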
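#' @import methods
NULL

#' Land-class coding used throughout the package
#'
#' Categorical rasters code the seven land classes as integers:
#' 1 cultivated, 2 grassland, 3 forest, 4 water, 5 garden, 6 construction,
#' 7 other; 0 is nodata. The same labels index coefficient tables, demand
#' vectors and area reports.
#'
#' @return Named integer vector mapping class labels to raster codes.
#' @examples
#' landClasses()
#' @export
landClasses <- function() {
  c(cultivated = 1L, grassland = 2L, forest = 3L, water = 4L,
    garden = 5L, construction = 6L, other = 7L)
}

NODATA_CODE <- 0L

#' GridSpec: geometry of a regular raster grid
#'
#' Row-major, north-up grid with square cells and origin at the top-left
#' corner. Areas are cell counts times \code{cellSize^2}, reported in km2.
#'
#' @slot nrows,ncols integer grid dimensions.
#' @slot cellSize numeric, metres per cell side.
#' @slot origin numeric length-2, (x, y) of the top-left corner.
#' @slot crs free-text label of the coordinate system.
#'
#' @exportClass GridSpec
setClass("GridSpec",
  representation(nrows = "integer", ncols = "integer",
                 cellSize = "numeric", origin = "numeric", crs = "character"),
  prototype(nrows = 1L, ncols = 1L, cellSize = 10, origin = c(0, 0),
            crs = "local-metric"))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nrows) != 1L || length(object@ncols) != 1L ||
      is.na(object@nrows) || is.na(object@ncols) ||
      object@nrows < 1L || object@ncols < 1L)
    msg <- c(msg, "nrows and ncols must be positive integers")
  else if (object@nrows * object@ncols < 4)
    msg <- c(msg, "grid must have at least 4 cells")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a positive number (metres)")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be a finite (x, y) pair")
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param nrows,ncols grid dimensions.
#' @param cellSize cell side length in metres (default 10, i.e. 100 m2 cells).
#' @param origin top-left corner coordinates.
#' @param crs coordinate-system label (free text).
#' @return A \linkS4class{GridSpec}.
#' @examples
#' GridSpec(50, 50, cellSize = 10)
#' @export
GridSpec <- function(nrows, ncols, cellSize = 10, origin = c(0, 0),
                     crs = "local-metric") {
  new("GridSpec", nrows = as.integer(nrows), ncols = as.integer(ncols),
      cellSize = as.numeric(cellSize), origin = as.numeric(origin),
      crs = as.character(crs))
}

#' LandUseRaster: categorical land-use grid
#'
#' @slot grid a \linkS4class{GridSpec}.
#' @slot data integer matrix of class codes in 0..7 (0 = nodata), dimensions
#'   \code{nrows x ncols}.
#' @exportClass LandUseRaster
setClass("LandUseRaster",
  representation(grid = "GridSpec", data = "matrix"))

setValidity("LandUseRaster", function(object) {
  d <- object@data
  if (!is.integer(d[1L]) && !all(d == round(d), na.rm = TRUE))
    return("class codes must be integers")
  if (nrow(d) != object@grid@nrows || ncol(d) != object@grid@ncols)
    return("data dimensions do not match grid")
  if (any(d < 0L | d > 7L, na.rm = TRUE))
    return("class codes must lie in 0..7")
  if (!any(d != NODATA_CODE))
    return("raster must contain at least one non-nodata cell")
  TRUE
})

#' Construct a LandUseRaster
#' @param data integer matrix of class codes (0 = nodata).
#' @param grid a \linkS4class{GridSpec}; defaults to a grid matching
#'   \code{dim(data)} with 10 m cells.
#' @return A \linkS4class{LandUseRaster}.
#' @export
LandUseRaster <- function(data, grid = GridSpec(nrow(data), ncol(data))) {
  storage.mode(data) <- "integer"
  new("LandUseRaster", grid = grid, data = data)
}

#' DriverStack: named continuous driver rasters on a shared grid
#'
#' @slot grid a \linkS4class{GridSpec}.
#' @slot layers named list of numeric matrices, all of grid dimensions.
#' @slot normalized logical; TRUE once layers are min-max scaled to [0, 1].
#' @exportClass DriverStack
setClass("DriverStack",
  representation(grid = "GridSpec", layers = "list", normalized = "logical"),
  prototype(normalized = FALSE))

setValidity("DriverStack", function(object) {
  if (length(object@layers) < 1L) return("at least one driver layer required")
  nm <- names(object@layers)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    return("layers must have unique non-empty names")
  dims <- vapply(object@layers, dim, integer(2))
  if (any(dims[1, ] != object@grid@nrows) || any(dims[2, ] != object@grid@ncols))
    return("all layers must match the grid dimensions")
  if (isTRUE(object@normalized)) {
    rng <- range(unlist(lapply(object@layers, range, na.rm = TRUE)))
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      return("normalized stack has values outside [0, 1]")
  }
  TRUE
})

#' Construct a DriverStack
#' @param layers named list of numeric matrices.
#' @param grid a \linkS4class{GridSpec}.
#' @param normalized whether the layers are already min-max scaled.
#' @return A \linkS4class{DriverStack}.
#' @export
DriverStack <- function(layers, grid = GridSpec(nrow(layers[[1]]), ncol(layers[[1]])),
                        normalized = FALSE) {
  new("DriverStack", grid = grid, layers = layers, normalized = normalized)
}

#' ZonePartition: rasterized zone tessellation with zone attributes
#'
#' Every cell belongs to exactly one zone (integer id >= 1). Zone-level
#' attributes (diversity area, ESV, ...) live in \code{table}, keyed by
#' \code{zone_id}.
#'
#' @slot grid a \linkS4class{GridSpec}.
#' @slot zoneIds integer matrix of zone ids (>= 1) of grid dimensions.
#' @slot table data.frame with a \code{zone_id} column and attached values.
#' @exportClass ZonePartition
setClass("ZonePartition",
  representation(grid = "GridSpec", zoneIds = "matrix", table = "data.frame"))

setValidity("ZonePartition", function(object) {
  z <- object@zoneIds
  if (nrow(z) != object@grid@nrows || ncol(z) != object@grid@ncols)
    return("zoneIds dimensions do not match grid")
  if (any(z < 1L, na.rm = TRUE)) return("zone ids must be >= 1")
  if (!"zone_id" %in% names(object@table))
    return("table must carry a zone_id column")
  if (anyDuplicated(object@table$zone_id))
    return("zone_id values must be unique")
  if (!all(unique(as.vector(z)) %in% object@table$zone_id))
    return("every rasterized zone id must appear in the table")
  TRUE
})

#' Construct a ZonePartition
#' @param zoneIds integer matrix of zone labels (>= 1).
#' @param grid a \linkS4class{GridSpec}.
#' @param table zone attribute data.frame; defaults to the bare id list.
#' @return A \linkS4class{ZonePartition}.
#' @export
ZonePartition <- function(zoneIds, grid = GridSpec(nrow(zoneIds), ncol(zoneIds)),
                          table = NULL) {
  storage.mode(zoneIds) <- "integer"
  if (is.null(table))
    table <- data.frame(zone_id = sort(unique(as.vector(zoneIds))))
  new("ZonePartition", grid = grid, zoneIds = zoneIds, table = table)
}

#' PotentialSurfaces: per-class development-probability rasters
#'
#' Output of the land-expansion analysis: for each land class a raster of
#' expansion probability in [0, 1], plus normalized per-driver importance
#' scores (contribution of each driver to that class's expansion).
#'
#' @slot grid a \linkS4class{GridSpec}.
#' @slot surfaces named list ("1".."7") of probability matrices.
#' @slot contributions named list of per-driver importance vectors, each
#'   nonnegative and summing to 1 (or NA for classes fit with a flat surface).
#' @exportClass PotentialSurfaces
setClass("PotentialSurfaces",
  representation(grid = "GridSpec", surfaces = "list", contributions = "list"))

setValidity("PotentialSurfaces", function(object) {
  for (k in names(object@surfaces)) {
    s <- object@surfaces[[k]]
    if (nrow(s) != object@grid@nrows || ncol(s) != object@grid@ncols)
      return(sprintf("surface %s does not match the grid", k))
    if (any(s < -1e-9 | s > 1 + 1e-9, na.rm = TRUE))
      return(sprintf("surface %s has probabilities outside [0, 1]", k))
    imp <- object@contributions[[k]]
    if (!is.null(imp) && !anyNA(imp)) {
      if (any(imp < -1e-9)) return("importances must be nonnegative")
      if (abs(sum(imp) - 1) > 1e-9)
        return(sprintf("importances for class %s must sum to 1", k))
    }
  }
  TRUE
})

#' SyntheticScene: a generated landscape with known truth
#'
#' @slot luT0,luT1 \linkS4class{LandUseRaster} pair (before / after).
#' @slot drivers \linkS4class{DriverStack}.
#' @slot restriction integer matrix, 1 = change forbidden.
#' @slot zones \linkS4class{ZonePartition}.
#' @slot truth list: the generating configuration (class proportions,
#'   transition counts, driver effects, seed).
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(luT0 = "LandUseRaster", luT1 = "LandUseRaster",
                 drivers = "DriverStack", restriction = "matrix",
                 zones = "ZonePartition", truth = "list"))

setValidity("SyntheticScene", function(object) {
  g <- object@luT0@grid
  if (g@nrows != object@luT1@grid@nrows || g@ncols != object@luT1@grid@ncols)
    return("luT0 and luT1 must share a grid")
  changed <- object@luT0@data != object@luT1@data
  if (any(changed & object@restriction == 1L))
    return("restricted cells must not change class")
  TRUE
})

#' ScenarioSpec: growth-rate scenario parameters
#'
#' @slot name scenario label (e.g. "low", "medium", "high").
#' @slot gdpRate annual GDP change rate as a fraction (0.08 = 8 percent/yr).
#' @slot popRate annual population change rate as a fraction.
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  representation(name = "character", gdpRate = "numeric", popRate = "numeric"))

setValidity("ScenarioSpec", function(object) {
  if (!nzchar(object@name)) return("scenario needs a name")
  if (!is.finite(object@gdpRate) || !is.finite(object@popRate))
    return("rates must be finite")
  TRUE
})

#' Construct a ScenarioSpec
#' @param name scenario label.
#' @param gdpRate,popRate annual change rates as fractions per year.
#' @return A \linkS4class{ScenarioSpec}.
#' @examples
#' ScenarioSpec("low", gdpRate = 0.08, popRate = 0.0022)
#' @export
ScenarioSpec <- function(name, gdpRate, popRate) {
  new("ScenarioSpec", name = name, gdpRate = gdpRate, popRate = popRate)
}

#' SpatialWeights: zone-to-zone spatial weight matrix
#'
#' @slot ids integer zone ids, in matrix order.
#' @slot w numeric weight matrix (zero diagonal).
#' @slot scheme "queen", "rook" or "knn".
#' @slot rowStandardized logical.
#' @exportClass SpatialWeights
setClass("SpatialWeights",
  representation(ids = "integer", w = "matrix", scheme = "character",
                 rowStandardized = "logical"))

setValidity("SpatialWeights", function(object) {
  if (nrow(object@w) != length(object@ids) ||
      ncol(object@w) != length(object@ids))
    return("weight matrix does not match ids")
  if (any(diag(object@w) != 0)) return("self-weights are not allowed")
  if (isTRUE(object@rowStandardized)) {
    rs <- rowSums(object@w)
    if (any(abs(rs[rs > 0] - 1) > 1e-9))
      return("row-standardized rows must sum to 1")
  }
  TRUE
})
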
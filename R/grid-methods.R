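#' Grid accessor
#'
#' @param x an object carrying a \linkS4class{GridSpec}.
#' @return The \linkS4class{GridSpec}.
#' @rdname gridSpec
#' @export
setMethod("gridSpec", "LandUseRaster", function(x) x@grid)

#' @rdname gridSpec
#' @export
setMethod("gridSpec", "DriverStack", function(x) x@grid)

#' @rdname gridSpec
#' @export
setMethod("gridSpec", "ZonePartition", function(x) x@grid)

#' @rdname gridSpec
#' @export
setMethod("gridSpec", "PotentialSurfaces", function(x) x@grid)

#' Raster payload accessor
#'
#' @param x a \linkS4class{LandUseRaster} or \linkS4class{ZonePartition}.
#' @return The underlying integer matrix.
#' @rdname rasterData
#' @export
setMethod("rasterData", "LandUseRaster", function(x) x@data)

#' @rdname rasterData
#' @export
setMethod("rasterData", "ZonePartition", function(x) x@zoneIds)

#' Cell area in km2 for a grid
#' @param grid a \linkS4class{GridSpec}.
#' @return Area of one cell in km2.
#' @export
cellAreaKm2 <- function(grid) grid@cellSize^2 / 1e6

#' Driver layer access
#' @param x a \linkS4class{DriverStack}.
#' @return Named list of layer matrices.
#' @export
driverLayers <- function(x) x@layers

#' Per-class potential surface access
#' @param x a \linkS4class{PotentialSurfaces}.
#' @param class integer class code.
#' @return Probability matrix for that class.
#' @export
potentialSurface <- function(x, class) x@surfaces[[as.character(class)]]

#' Per-class driver contribution scores
#' @param x a \linkS4class{PotentialSurfaces}.
#' @return Named list of normalized importance vectors, one per fitted class.
#' @export
driverContributions <- function(x) x@contributions

#' Zone attribute table access
#' @param x a \linkS4class{ZonePartition}.
#' @return The zone attribute data.frame.
#' @export
zoneTable <- function(x) x@table

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells, %.6g m cells, origin (%.6g, %.6g), crs '%s'\n",
              object@nrows, object@ncols, object@cellSize,
              object@origin[1], object@origin[2], object@crs))
})

setMethod("show", "LandUseRaster", function(object) {
  tab <- table(factor(object@data[object@data != NODATA_CODE],
                      levels = landClasses()))
  cat(sprintf("LandUseRaster: %d x %d cells (%.6g m)\n",
              object@grid@nrows, object@grid@ncols, object@grid@cellSize))
  cat("  cells per class:",
      paste(sprintf("%s=%d", names(landClasses()), as.integer(tab)),
            collapse = " "), "\n")
})

setMethod("show", "DriverStack", function(object) {
  cat(sprintf("DriverStack: %d layer(s) [%s] on %d x %d grid%s\n",
              length(object@layers), paste(names(object@layers), collapse = ", "),
              object@grid@nrows, object@grid@ncols,
              if (object@normalized) ", normalized" else ""))
})

setMethod("show", "ZonePartition", function(object) {
  cat(sprintf("ZonePartition: %d zones on %d x %d grid, %d attribute column(s)\n",
              nrow(object@table), object@grid@nrows, object@grid@ncols,
              ncol(object@table) - 1L))
})

setMethod("show", "PotentialSurfaces", function(object) {
  cat(sprintf("PotentialSurfaces: classes [%s] on %d x %d grid\n",
              paste(names(object@surfaces), collapse = ", "),
              object@grid@nrows, object@grid@ncols))
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec '%s': GDP %+.2f%%/yr, population %+.2f%%/yr\n",
              object@name, 100 * object@gdpRate, 100 * object@popRate))
})

#' @rdname areasFromRaster
#' @export
setMethod("areasFromRaster", "LandUseRaster", function(lu) {
  counts <- tabulate(lu@data[lu@data != NODATA_CODE], nbins = 7L)
  stats::setNames(counts * cellAreaKm2(lu@grid), names(landClasses()))
})

## internal: shared-grid check used across modules
sameGrid <- function(a, b) {
  a@nrows == b@nrows && a@ncols == b@ncols &&
    isTRUE(all.equal(a@cellSize, b@cellSize))
}
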
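#' @rdname gridSpec
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname rasterData
#' @export
setGeneric("rasterData", function(x) standardGeneric("rasterData"))

#' Per-class areas of a land-use raster
#'
#' Counts cells per land class and converts to km2
#' (\code{count * cellSize^2 / 1e6}). Nodata cells are excluded.
#'
#' @param lu a \linkS4class{LandUseRaster}.
#' @return Named numeric vector of areas (km2) over the seven classes.
#' @examples
#' lu <- LandUseRaster(matrix(3L, 100, 100))  # 10 m cells
#' areasFromRaster(lu)[["forest"]]            # 1 km2
#' @export
setGeneric("areasFromRaster", function(lu) standardGeneric("areasFromRaster"))
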
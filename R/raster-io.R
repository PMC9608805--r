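## Raster, zone and table I/O.
##
## Rasters are serialized as ESRI ASCII grids (.asc) - a plain-text,
## widely supported single-band raster format: categorical land-use grids
## with NODATA_value 0, continuous drivers at full double precision.
## Zones travel as GeoJSON FeatureCollections (one MultiPolygon of
## grid-aligned cell squares per zone, attributes on the feature).

#' Write a raster matrix as an ESRI ASCII grid
#'
#' @param data numeric or integer matrix (row 1 = northernmost row).
#' @param grid a \linkS4class{GridSpec}.
#' @param path output file path.
#' @param nodata value to declare as NODATA (default 0 for categorical, use
#'   e.g. -9999 for continuous layers).
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(data, grid, path, nodata = 0) {
  stopifnot(nrow(data) == grid@nrows, ncol(data) == grid@ncols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid@ncols),
    sprintf("nrows %d", grid@nrows),
    sprintf("xllcorner %.10g", grid@origin[1]),
    sprintf("yllcorner %.10g", grid@origin[2] - grid@nrows * grid@cellSize),
    sprintf("cellsize %.10g", grid@cellSize),
    sprintf("NODATA_value %.10g", nodata)), con)
  utils::write.table(format(data, trim = TRUE, digits = 17, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param crs coordinate-system label to attach (the .asc format carries none).
#' @return List with \code{data} (numeric matrix), \code{grid}
#'   (\linkS4class{GridSpec}) and \code{nodata}.
#' @export
readAsciiGrid <- function(path, crs = "local-metric") {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "[[:space:]]+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys))
    stop("malformed ASCII grid header in '", path, "'")
  nr <- as.integer(vals["nrows"]); nc <- as.integer(vals["ncols"])
  body <- scan(path, skip = 6L, quiet = TRUE)
  if (length(body) != nr * nc)
    stop("ASCII grid '", path, "' has ", length(body),
         " values, expected ", nr * nc)
  grid <- GridSpec(nr, nc, cellSize = vals["cellsize"],
                   origin = c(vals["xllcorner"],
                              vals["yllcorner"] + nr * vals["cellsize"]),
                   crs = crs)
  list(data = matrix(body, nrow = nr, ncol = nc, byrow = TRUE),
       grid = grid, nodata = unname(vals["nodata_value"]))
}

#' Write / read a LandUseRaster
#' @param lu a \linkS4class{LandUseRaster}.
#' @param path file path (.asc).
#' @return \code{writeLandUse}: the path, invisibly. \code{readLandUse}: a
#'   \linkS4class{LandUseRaster}.
#' @export
writeLandUse <- function(lu, path) writeAsciiGrid(lu@data, lu@grid, path, 0)

#' @rdname writeLandUse
#' @export
readLandUse <- function(path) {
  g <- readAsciiGrid(path)
  m <- g$data
  if (any(m != round(m) | m < 0 | m > 7, na.rm = TRUE))
    stop("'", path, "' is not a 7-class land-use raster (codes 0..7)")
  LandUseRaster(matrix(as.integer(m), nrow(m), ncol(m)), g$grid)
}

#' Write / read a DriverStack as one .asc per layer
#' @param stack a \linkS4class{DriverStack}.
#' @param dir directory for the layer files (\code{<name>.asc}).
#' @param paths for \code{readDriverStack}: named character vector of .asc
#'   paths (names become layer names).
#' @param normalized whether the layers being read are min-max scaled.
#' @return \code{writeDriverStack}: named vector of written paths.
#'   \code{readDriverStack}: a \linkS4class{DriverStack}.
#' @export
writeDriverStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- vapply(names(stack@layers), function(nm) {
    writeAsciiGrid(stack@layers[[nm]], stack@grid,
                   file.path(dir, paste0(nm, ".asc")), nodata = -9999)
  }, "")
  invisible(out)
}

#' @rdname writeDriverStack
#' @export
readDriverStack <- function(paths, normalized = FALSE) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.asc$", "", basename(paths))
  reads <- lapply(paths, readAsciiGrid)
  grid <- reads[[1]]$grid
  DriverStack(lapply(reads, `[[`, "data"), grid, normalized = normalized)
}

## cell square polygon in grid coordinates (ring closed, counter-clockwise)
.cellSquare <- function(row, col, grid) {
  x0 <- grid@origin[1] + (col - 1) * grid@cellSize
  y0 <- grid@origin[2] - (row - 1) * grid@cellSize  # top edge
  s <- grid@cellSize
  list(list(c(x0, y0 - s), c(x0 + s, y0 - s), c(x0 + s, y0), c(x0, y0),
            c(x0, y0 - s)))
}

#' Write a ZonePartition as GeoJSON
#'
#' Each zone becomes one Feature whose geometry is a MultiPolygon of its
#' grid-aligned cell squares and whose properties carry \code{zone_id} plus
#' any attached attribute columns. Grid metadata is stored in a foreign
#' \code{grid} member so the partition round-trips losslessly.
#'
#' @param zones a \linkS4class{ZonePartition}.
#' @param path output .geojson path.
#' @return \code{path}, invisibly.
#' @export
writeZonesGeoJSON <- function(zones, path) {
  g <- zones@grid
  tab <- zones@table
  feats <- lapply(seq_len(nrow(tab)), function(i) {
    zid <- tab$zone_id[i]
    idx <- which(zones@zoneIds == zid, arr.ind = TRUE)
    polys <- lapply(seq_len(nrow(idx)), function(j)
      .cellSquare(idx[j, 1], idx[j, 2], g))
    props <- as.list(tab[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  obj <- list(type = "FeatureCollection",
              grid = list(nrows = g@nrows, ncols = g@ncols,
                          cellSize = g@cellSize, origin = g@origin,
                          crs = g@crs),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ZonePartition from GeoJSON written by writeZonesGeoJSON
#' @param path .geojson path.
#' @return A \linkS4class{ZonePartition}.
#' @export
readZonesGeoJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$grid))
    stop("'", path, "' lacks the grid member; not a landplus zone file")
  gi <- obj$grid
  grid <- GridSpec(gi$nrows, gi$ncols, gi$cellSize,
                   origin = unlist(gi$origin), crs = gi$crs)
  ids <- matrix(NA_integer_, grid@nrows, grid@ncols)
  rows <- list()
  for (f in obj$features) {
    props <- lapply(f$properties, function(p) if (is.null(p)) NA else p)
    zid <- as.integer(props$zone_id)
    for (poly in f$geometry$coordinates) {
      ring <- poly[[1]]
      ## centroid of the square locates the cell
      cx <- mean(vapply(ring[1:4], function(p) p[[1]], 0))
      cy <- mean(vapply(ring[1:4], function(p) p[[2]], 0))
      col <- as.integer(floor((cx - grid@origin[1]) / grid@cellSize)) + 1L
      row <- as.integer(floor((grid@origin[2] - cy) / grid@cellSize)) + 1L
      ids[row, col] <- zid
    }
    rows[[length(rows) + 1L]] <- as.data.frame(props)
  }
  if (anyNA(ids)) stop("zone polygons in '", path, "' do not cover the grid")
  tab <- do.call(rbind, rows)
  tab$zone_id <- as.integer(tab$zone_id)
  ZonePartition(ids, grid, table = tab)
}

#' Read a per-class area CSV (`land_type,area_km2`)
#' @param path CSV path.
#' @return Named numeric area vector over the seven land classes (km2).
#' @export
readAreaCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("land_type", "area_km2") %in% names(df)))
    stop("area CSV must have columns land_type, area_km2")
  bad <- setdiff(df$land_type, names(landClasses()))
  if (length(bad))
    stop("unknown land-type label(s): ", paste(bad, collapse = ", "))
  areas <- stats::setNames(numeric(7), names(landClasses()))
  areas[df$land_type] <- df$area_km2
  areas
}

#' Write a per-class area vector as CSV
#' @param areas named numeric vector (km2) over land classes.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeAreaCSV <- function(areas, path) {
  utils::write.csv(data.frame(land_type = names(areas),
                              area_km2 = as.numeric(areas)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
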
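## Equivalent-factor ecosystem-services valuation.
##
## One "equivalent" is a fixed fraction (1/divisor, conventionally 1/7) of
## the regional grain economic output per hectare; every service x
## land-type coefficient is a multiple of it. Valuation is then the linear
## form ESV = sum_k A_k (ha) x VC_k (yuan/ha).

#' Regional value of one standard equivalent
#'
#' \code{grainYield x grainPrice / divisor} in yuan/ha. The conventional
#' divisor 7 treats one equivalent as one seventh of the grain economic
#' output per hectare; it is a default, not hard-coded.
#'
#' @param grainYield average grain yield, kg/ha.
#' @param grainPrice average grain price, yuan/kg.
#' @param divisor dimensionless (> 0, default 7).
#' @return yuan/ha.
#' @examples
#' regionalEquivalent(5968.322, 2.44)  # 2080.386 yuan/ha
#' @export
regionalEquivalent <- function(grainYield, grainPrice, divisor = 7) {
  if (divisor <= 0) stop("divisor must be positive")
  stopifnot(grainYield >= 0, grainPrice >= 0)
  grainYield * grainPrice / divisor
}

## align a km2 area vector with the coefficient table columns
.alignAreas <- function(areas, vc) {
  if (is.null(names(areas)))
    stop("areas must be a named vector over land types")
  unmatched <- setdiff(names(areas), colnames(vc))
  if (length(unmatched))
    stop("land-type label(s) not in the coefficient table: ",
         paste(unmatched, collapse = ", "))
  full <- stats::setNames(numeric(ncol(vc)), colnames(vc))
  full[names(areas)] <- areas
  full
}

#' Total ecosystem-services value of an area vector
#'
#' \code{sum_k A_k (ha) x VC_k}; areas are supplied in km2 and converted
#' (x 100) to ha. The per-land-type coefficient is the column sum over the
#' service rows, so the total is exactly consistent with the marginals of
#' \code{\link{esvMatrix}} (the audited printed column totals agree with
#' these sums to within their rounding drift).
#'
#' @param areas named per-land-type areas in km2.
#' @param vc coefficient matrix from \code{\link{esvCoefficients}}.
#' @return Total value in yuan.
#' @examples
#' esvTotal(landDemand2035("low"))  / 1e8  # 70.01 (10^8 yuan)
#' @export
esvTotal <- function(areas, vc = esvCoefficients()) {
  a <- .alignAreas(areas, vc)
  sum(a * 100 * colSums(vc))
}

#' Full service-by-land-type value matrix
#'
#' @param areas named per-land-type areas in km2.
#' @param vc coefficient matrix from \code{\link{esvCoefficients}}.
#' @return An \code{ESVReport}: the service x land-type value matrix in
#'   yuan, with attributes \code{by_service}, \code{by_land_type} and
#'   \code{total} (all yuan).
#' @export
esvMatrix <- function(areas, vc = esvCoefficients()) {
  a <- .alignAreas(areas, vc)
  m <- sweep(vc, 2, a * 100, `*`)
  structure(m, by_service = rowSums(m), by_land_type = colSums(m),
            total = sum(m), class = c("ESVReport", class(m)))
}

#' Round a yuan value to the display convention
#'
#' Reports values in 10^8 yuan with half-up rounding to 2 decimals, the
#' convention of the printed tables (base R \code{round} rounds half to
#' even, so a dedicated half-up helper is used).
#'
#' @param yuan value(s) in yuan.
#' @return Value(s) in 10^8 yuan rounded half-up to 2 decimals.
#' @export
esvDisplay <- function(yuan) {
  x <- yuan / 1e8
  trunc(x * 100 + 0.5 * sign(x)) / 100
}

#' Change between two ESV reports
#'
#' Per entry (and per marginal) the absolute change \code{b - a} and the
#' percent change \code{(b - a)/a x 100}; entries with a zero baseline get
#' \code{NA} percent change.
#'
#' @param a baseline \code{ESVReport}.
#' @param b comparison \code{ESVReport}.
#' @return List with matrices \code{delta} and \code{pct}, plus
#'   \code{total_delta} and \code{total_pct} (yuan, percent).
#' @export
esvChange <- function(a, b) {
  stopifnot(identical(dimnames(a), dimnames(b)))
  d <- unclass(b) - unclass(a)
  pct <- ifelse(unclass(a) == 0, NA_real_, d / unclass(a) * 100)
  ta <- attr(a, "total"); tb <- attr(b, "total")
  list(delta = d, pct = pct, total_delta = tb - ta,
       total_pct = if (ta == 0) NA_real_ else (tb - ta) / ta * 100)
}

#' Per-zone ecosystem-services value of a land-use raster
#'
#' Builds each zone's per-class area vector and applies
#' \code{\link{esvTotal}}; zonal values add up to the whole-map total.
#'
#' @param lu a \linkS4class{LandUseRaster}.
#' @param zones a \linkS4class{ZonePartition} covering the raster.
#' @param vc coefficient matrix from \code{\link{esvCoefficients}}.
#' @return data.frame \code{zone_id, esv_yuan}.
#' @export
zonalESV <- function(lu, zones, vc = esvCoefficients()) {
  stopifnot(sameGrid(lu@grid, zones@grid))
  cellArea <- cellAreaKm2(lu@grid)
  zids <- zones@table$zone_id
  vals <- vapply(zids, function(z) {
    sel <- zones@zoneIds == z & lu@data != NODATA_CODE
    if (!any(sel)) {
      message("zone ", z, " has no valid cells; value 0")
      return(0)
    }
    counts <- tabulate(lu@data[sel], nbins = 7L)
    areas <- stats::setNames(counts * cellArea, names(landClasses()))
    esvTotal(areas, vc)
  }, 0)
  data.frame(zone_id = zids, esv_yuan = vals)
}
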
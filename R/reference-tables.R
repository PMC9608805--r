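## Built-in reference tables: the equivalent-factor coefficient table,
## the demand-model validation series, scenario growth rates, and the
## 2035 per-scenario land-demand areas used in the worked examples.

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "landplus")
  if (!nzchar(p)) stop("built-in table '", file, "' not found")
  p
}

#' Load a service-by-land-type ESV coefficient table from CSV
#'
#' The CSV mirrors the standard equivalent-factor layout: one row per
#' ecosystem service plus a \code{total} row, one column per land class
#' (construction all zero). On load the column totals are audited against
#' the \code{total} row to within 0.025 yuan/ha, guarding transcription
#' errors while tolerating the drift left by tables whose printed rows
#' were rounded independently of the total; the audited \code{total} row
#' (the authoritative per-land-type coefficient) is then dropped.
#'
#' @param path CSV path; defaults to the built-in coefficient table.
#' @return Numeric matrix (services x 7 land types), yuan/ha, with a
#'   \code{"total"} attribute carrying the audited column totals.
#' @examples
#' vc <- esvCoefficients()
#' attr(vc, "total")[["forest"]]  # 46620.78 yuan/ha
#' @export
esvCoefficients <- function(path = .extdata("esv_coefficients.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "service")
    stop("coefficient CSV must start with a 'service' column")
  types <- names(df)[-1]
  bad <- setdiff(types, names(landClasses()))
  if (length(bad))
    stop("unknown land-type column(s): ", paste(bad, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$service
  if (!"total" %in% rownames(m))
    stop("coefficient CSV must include a 'total' row")
  totals <- m["total", ]
  m <- m[rownames(m) != "total", , drop = FALSE]
  if (any(m < 0)) stop("coefficients must be nonnegative")
  drift <- abs(colSums(m) - totals)
  if (any(drift > 0.025))
    stop("column totals disagree with the table's total row for: ",
         paste(names(which(drift > 0.01)), collapse = ", "))
  ## fixed column order matching the package class coding
  m <- m[, names(landClasses())[names(landClasses()) %in% colnames(m)],
         drop = FALSE]
  attr(m, "total") <- totals[colnames(m)]
  m
}

#' Historical vs simulated validation series for the demand model
#'
#' Eight-year series (2011-2018) of historical and simulated values for the
#' four validation indicators of the land-use system-dynamics model: total
#' population (persons), construction, cultivated and forest land (km2).
#'
#' @return data.frame with columns indicator, year, historical, simulated.
#' @export
sdValidationSeries <- function() {
  utils::read.csv(.extdata("sd_validation_series.csv"),
                  stringsAsFactors = FALSE)
}

#' Growth-rate parameters of the three standard scenarios
#'
#' @return List of \linkS4class{ScenarioSpec} (high, medium, low) with the
#'   standard GDP change rates (13.66 / 10.40 / 8.00 percent per year) and
#'   population change rates (0.52 / 0.35 / 0.22 percent per year).
#' @export
standardScenarios <- function() {
  df <- utils::read.csv(.extdata("scenario_parameters.csv"),
                        stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    ScenarioSpec(df$scenario[i], df$gdp_change_rate_pct[i] / 100,
                 df$pop_change_rate_pct[i] / 100))
  stats::setNames(out, df$scenario)
}

#' Simulated 2035 land-class areas per scenario
#'
#' Per-scenario per-class areas (km2) at the 2035 horizon from the
#' system-dynamics demand model; inputs of the valuation worked examples.
#'
#' @param scenario optional scenario name ("low", "medium", "high"); if
#'   given, returns that scenario's named area vector in package class
#'   order, else the full data.frame.
#' @return Named numeric vector (km2) or data.frame.
#' @export
landDemand2035 <- function(scenario = NULL) {
  df <- utils::read.csv(.extdata("land_demand_2035.csv"),
                        stringsAsFactors = FALSE)
  if (is.null(scenario)) return(df)
  row <- df[df$scenario == scenario, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown scenario '", scenario, "'")
  v <- stats::setNames(numeric(7), names(landClasses()))
  for (nm in names(landClasses())) v[nm] <- row[[nm]]
  v
}
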
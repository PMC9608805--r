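## System-dynamics land-demand model.
##
## Stocks (population, urban population, GDP) advance by annual Euler steps
## at their scenario rates; fixed-asset investment closes as a fixed share
## of GDP; construction-land demand is a linear function of urban
## population and investment anchored at the base year; growth of
## construction land is debited from the remaining classes by configurable
## donor weights so that total area is conserved.

#' SDParams: parameters of the land-demand model
#'
#' @slot baseYear integer base year of the simulation.
#' @slot scon0 construction-land area at the base year (km2).
#' @slot pop0,urpop0 total and urban population at the base year (persons).
#' @slot gdp0 GDP at the base year (monetary units; the same unit must be
#'   used for investment, see \code{investCoeff}).
#' @slot urpopCoeff km2 per person of urban population (default -3.35e-5).
#' @slot investCoeff km2 per monetary unit of fixed-asset investment
#'   (default 5.727e-6).
#' @slot investGdpRatio investment as a share of GDP (dimensionless).
#' @slot donorWeights named weights over the six non-construction classes,
#'   summing to 1: the share of each year's construction growth debited
#'   from (negative = credited to) each class.
#' @slot classRates named per-class intrinsic annual change rates
#'   (fractions); empty = none.
#' @slot areas0 named per-class areas at the base year (km2); its
#'   construction entry must equal \code{scon0}.
#' @exportClass SDParams
setClass("SDParams",
  representation(baseYear = "integer", scon0 = "numeric", pop0 = "numeric",
                 urpop0 = "numeric", gdp0 = "numeric",
                 urpopCoeff = "numeric", investCoeff = "numeric",
                 investGdpRatio = "numeric", donorWeights = "numeric",
                 classRates = "numeric", areas0 = "numeric"))

setValidity("SDParams", function(object) {
  msg <- character()
  if (object@scon0 <= 0) msg <- c(msg, "scon0 must be positive")
  if (abs(sum(object@donorWeights) - 1) > 1e-9)
    msg <- c(msg, "donorWeights must sum to 1")
  if (!setequal(names(object@donorWeights),
                setdiff(names(landClasses()), "construction")))
    msg <- c(msg, "donorWeights must be named over the six non-construction classes")
  if (!setequal(names(object@areas0), names(landClasses())))
    msg <- c(msg, "areas0 must be named over the seven classes")
  else if (abs(object@areas0[["construction"]] - object@scon0) > 1e-9)
    msg <- c(msg, "areas0['construction'] must equal scon0")
  if (any(object@areas0 < 0)) msg <- c(msg, "areas must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct SDParams
#'
#' Defaults describe a mountainous county of 1688 km2 observed in 2018:
#' 583,969 residents of whom 235,000 urban, GDP 1.83e6 (units of 1e4 yuan),
#' 162.05 km2 of construction land. When \code{investGdpRatio} is NULL it
#' is calibrated in closed form so that the low-growth scenario (8\%/yr
#' GDP, 0.22\%/yr population) reaches a 2035 construction-land demand of
#' 191.58 km2 (see \code{\link{calibrateInvestRatio}}).
#'
#' @param baseYear base year (default 2018).
#' @param areas0 named per-class base areas in km2.
#' @param pop0,urpop0,gdp0 base-year population, urban population, GDP.
#' @param urpopCoeff,investCoeff demand-equation coefficients.
#' @param investGdpRatio investment/GDP share, or NULL to calibrate.
#' @param donorWeights named weights over non-construction classes
#'   (sum 1); defaults debit growth mostly from forest and cultivated land
#'   and credit garden land, which expands with the planting industry.
#' @param classRates optional named intrinsic annual change rates.
#' @return An \linkS4class{SDParams}.
#' @examples
#' p <- SDParams()
#' p@investGdpRatio
#' @export
SDParams <- function(baseYear = 2018L,
                     areas0 = c(cultivated = 442.64, grassland = 0.60,
                                forest = 923.36, water = 95.00,
                                garden = 45.00, construction = 162.05,
                                other = 19.35),
                     pop0 = 583969, urpop0 = 235000, gdp0 = 1.83e6,
                     urpopCoeff = -3.35e-5, investCoeff = 5.727e-6,
                     investGdpRatio = NULL,
                     donorWeights = c(cultivated = 0.35, grassland = 0.08,
                                      forest = 0.45, water = 0.12,
                                      garden = -0.10, other = 0.10),
                     classRates = numeric()) {
  areas0 <- areas0[names(landClasses())]
  if (is.null(investGdpRatio))
    investGdpRatio <- calibrateInvestRatio(
      scon0 = areas0[["construction"]], urpop0 = urpop0, gdp0 = gdp0,
      urpopCoeff = urpopCoeff, investCoeff = investCoeff,
      scenario = ScenarioSpec("low", 0.08, 0.0022),
      horizonYears = 2035L - baseYear, target = 191.58)
  new("SDParams", baseYear = as.integer(baseYear),
      scon0 = areas0[["construction"]], pop0 = pop0, urpop0 = urpop0,
      gdp0 = gdp0, urpopCoeff = urpopCoeff, investCoeff = investCoeff,
      investGdpRatio = investGdpRatio, donorWeights = donorWeights,
      classRates = classRates, areas0 = areas0)
}

#' Calibrate the investment/GDP share against a demand target
#'
#' The construction-demand equation is linear in investment, so the
#' investment/GDP share that makes demand hit \code{target} at the horizon
#' under a given scenario has the closed form
#' \deqn{\rho = \frac{T - S_0 - c_u U_0 ((1+p)^H - 1)}{c_i G_0 ((1+g)^H - 1)}}
#' with demand anchored at the base year (increment form).
#'
#' @param scon0,urpop0,gdp0 base-year construction area, urban population,
#'   GDP.
#' @param urpopCoeff,investCoeff demand coefficients.
#' @param scenario a \linkS4class{ScenarioSpec}.
#' @param horizonYears number of annual steps to the horizon.
#' @param target construction-land demand (km2) at the horizon.
#' @return The investment/GDP share (dimensionless).
#' @export
calibrateInvestRatio <- function(scon0, urpop0, gdp0, urpopCoeff,
                                 investCoeff, scenario, horizonYears,
                                 target) {
  num <- target - scon0 -
    urpopCoeff * urpop0 * ((1 + scenario@popRate)^horizonYears - 1)
  den <- investCoeff * gdp0 * ((1 + scenario@gdpRate)^horizonYears - 1)
  if (abs(den) < .Machine$double.eps)
    stop("scenario produces no investment growth; ratio not identifiable")
  num / den
}

#' One annual Euler step of a stock
#'
#' @param value current stock value.
#' @param rate annual change rate as a fraction.
#' @return \code{value * (1 + rate)}.
#' @examples
#' integrateStock(583969, 0.0022)
#' @export
integrateStock <- function(value, rate) {
  stopifnot(is.finite(value))
  value * (1 + rate)
}

#' Construction-land demand from urban population and investment
#'
#' Linear demand equation \code{scon0 + urpopCoeff * urpop +
#' investCoeff * invest}, clamped at zero. The default coefficients are
#' -3.35e-5 km2/person and 5.727e-6 km2 per investment unit.
#'
#' @param scon0 anchor construction area (km2).
#' @param urpop urban population (persons).
#' @param invest fixed-asset investment (monetary units).
#' @param urpopCoeff,investCoeff equation coefficients.
#' @return Construction-land demand in km2 (>= 0).
#' @examples
#' constructionDemand(162.05, 100000, 1e6)  # 164.427
#' @export
constructionDemand <- function(scon0, urpop, invest,
                               urpopCoeff = -3.35e-5,
                               investCoeff = 5.727e-6) {
  stopifnot(scon0 > 0)
  max(0, scon0 + urpopCoeff * urpop + investCoeff * invest)
}

## debit `delta` km2 from donor classes by weight, clamping at zero area
## with renormalization of the remaining positive-weight donors.
.debitDonors <- function(areas, weights, delta) {
  warned <- FALSE
  ## negative weights are credits; apply them unconditionally
  credits <- weights[weights < 0]
  for (k in names(credits)) areas[k] <- areas[k] - credits[k] * delta
  remaining <- delta * (1 - sum(credits))       # what debits must remove
  w <- weights[weights > 0]
  while (remaining > 1e-12 && length(w)) {
    w <- w / sum(w)
    take <- w * remaining
    hit <- names(take)[take > areas[names(take)]]
    if (!length(hit)) {
      areas[names(take)] <- areas[names(take)] - take
      remaining <- 0
    } else {
      ## exhaust those classes, renormalize the rest
      warned <- TRUE
      remaining <- remaining - sum(areas[hit])
      areas[hit] <- 0
      w <- w[setdiff(names(w), hit)]
    }
  }
  if (remaining > 1e-9 && !length(w))
    stop("donor classes exhausted; construction demand infeasible")
  attr(areas, "exhausted") <- warned
  areas
}

## apply intrinsic per-class rates, offsetting the net change against the
## classes without an intrinsic rate (proportionally to area) so that the
## total stays conserved.
.applyIntrinsicRates <- function(areas, rates) {
  if (!length(rates)) return(areas)
  delta <- areas[names(rates)] * rates
  areas[names(rates)] <- areas[names(rates)] + delta
  rest <- setdiff(names(areas), names(rates))
  if (!length(rest))
    stop("intrinsic rates on every class cannot conserve total area")
  share <- areas[rest] / sum(areas[rest])
  areas[rest] <- areas[rest] - share * sum(delta)
  pmax(areas, 0)
}

#' Run a growth scenario of the land-demand model
#'
#' Iterates annual steps from the base year to the horizon: population,
#' urban population and GDP advance by their scenario rates
#' (\code{\link{integrateStock}}); investment is
#' \code{investGdpRatio * GDP}; construction-land demand follows
#' \code{\link{constructionDemand}} anchored so that the base-year state
#' reproduces \code{scon0} exactly; each year's construction growth is
#' debited from the donor classes; optional intrinsic class rates are
#' applied. Total area is conserved throughout.
#'
#' @param params an \linkS4class{SDParams}.
#' @param scenario a \linkS4class{ScenarioSpec}.
#' @param horizonYear final simulated year (> base year).
#' @return A \code{DemandTrajectory}: data.frame with one row per year
#'   (base..horizon) and columns year, total_population, urban_population,
#'   gdp, investment, then the seven class areas (km2); the scenario is
#'   attached as attribute \code{"scenario"}.
#' @examples
#' traj <- runScenario(SDParams(), ScenarioSpec("low", 0.08, 0.0022), 2035)
#' tail(traj, 1)[["construction"]]  # ~191.58 km2 under defaults
#' @export
runScenario <- function(params, scenario, horizonYear) {
  stopifnot(horizonYear > params@baseYear)
  years <- params@baseYear:horizonYear
  n <- length(years)
  invest0 <- params@investGdpRatio * params@gdp0
  ## anchor such that the base-year demand equals scon0 (increment form)
  anchor <- params@scon0 - params@urpopCoeff * params@urpop0 -
    params@investCoeff * invest0
  pop <- params@pop0; urpop <- params@urpop0; gdp <- params@gdp0
  areas <- params@areas0
  anyExhausted <- FALSE
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      pop <- integrateStock(pop, scenario@popRate)
      urpop <- integrateStock(urpop, scenario@popRate)
      gdp <- integrateStock(gdp, scenario@gdpRate)
      invest <- params@investGdpRatio * gdp
      sconNew <- constructionDemand(anchor, urpop, invest,
                                    params@urpopCoeff, params@investCoeff)
      delta <- sconNew - areas[["construction"]]
      if (delta > 0) {
        donors <- areas[names(params@donorWeights)]
        donors <- .debitDonors(donors, params@donorWeights, delta)
        if (isTRUE(attr(donors, "exhausted"))) anyExhausted <- TRUE
        areas[names(donors)] <- as.numeric(donors)
      } else if (delta < 0) {
        ## shrinking construction returns land to donors by weight
        w <- params@donorWeights
        areas[names(w)] <- areas[names(w)] - w * delta
      }
      areas[["construction"]] <- sconNew
      areas <- .applyIntrinsicRates(areas, params@classRates)
    } else {
      invest <- invest0
    }
    out[[i]] <- c(year = years[i], total_population = pop,
                  urban_population = urpop, gdp = gdp, investment = invest,
                  areas)
  }
  if (anyExhausted)
    warning("donor class(es) exhausted during the run; weights ",
            "renormalized over the remaining donors", call. = FALSE)
  traj <- as.data.frame(do.call(rbind, out))
  attr(traj, "scenario") <- scenario
  class(traj) <- c("DemandTrajectory", "data.frame")
  traj
}

#' Per-class demand vector at a given year of a trajectory
#' @param traj a \code{DemandTrajectory} from \code{\link{runScenario}}.
#' @param year simulated year to extract.
#' @return Named numeric vector of class areas (km2).
#' @export
demandAt <- function(traj, year) {
  row <- traj[traj$year == year, , drop = FALSE]
  if (nrow(row) != 1L) stop("year ", year, " not in trajectory")
  unlist(row[1, names(landClasses())])
}

#' Relative error in percent
#'
#' \code{|sim - hist| / |hist| * 100}; the historical value is the
#' denominator.
#'
#' @param hist historical (reference) value, nonzero.
#' @param sim simulated value.
#' @return Relative error in percent.
#' @examples
#' relativeError(588358, 584438)  # 0.666... -> prints as 0.67
#' @export
relativeError <- function(hist, sim) {
  if (any(hist == 0)) stop("relative error undefined for zero historical value")
  abs(sim - hist) / abs(hist) * 100
}

#' Validate a demand trajectory against a historical series
#'
#' Computes per-year relative errors for the chosen indicators over the
#' overlapping years. The summary flag passes when construction errors stay
#' below 2 percent and all other indicators below 1 percent.
#'
#' @param traj a \code{DemandTrajectory}.
#' @param hist a historical series data.frame with a \code{year} column and
#'   columns matching the indicators.
#' @param indicators character vector of column names to compare (default:
#'   total population plus construction, cultivated and forest areas).
#' @return List with \code{table} (indicator, year, historical, simulated,
#'   rel_error_pct) and \code{pass} (logical).
#' @export
validateHistory <- function(traj, hist,
                            indicators = c("total_population", "construction",
                                           "cultivated", "forest")) {
  years <- intersect(traj$year, hist$year)
  if (!length(years)) stop("no overlapping years between trajectory and history")
  missing <- setdiff(indicators, intersect(names(traj), names(hist)))
  if (length(missing))
    stop("indicator(s) absent from inputs: ", paste(missing, collapse = ", "))
  rows <- do.call(rbind, lapply(indicators, function(ind) {
    h <- hist[[ind]][match(years, hist$year)]
    s <- traj[[ind]][match(years, traj$year)]
    data.frame(indicator = ind, year = years, historical = h, simulated = s,
               rel_error_pct = relativeError(h, s))
  }))
  limit <- ifelse(rows$indicator == "construction", 2, 1)
  list(table = rows, pass = all(rows$rel_error_pct < limit))
}

#' Relative-error table for printed historical/simulated pairs
#'
#' Convenience wrapper applying \code{\link{relativeError}} row-wise to a
#' validation series in the \code{\link{sdValidationSeries}} layout.
#'
#' @param series data.frame with columns indicator, year, historical,
#'   simulated.
#' @return The same data.frame with a \code{rel_error_pct} column appended.
#' @export
validationErrorTable <- function(series) {
  series$rel_error_pct <- relativeError(series$historical, series$simulated)
  series
}

#' Least-squares recovery of the demand-equation coefficients
#'
#' Fits \code{construction ~ urban_population + investment} by ordinary
#' least squares (the intercept absorbs the base-year anchor) and returns
#' the two slope coefficients. A regressor aliased by collinearity (e.g. a
#' constant urban-population series) is flagged unidentifiable.
#'
#' @param hist data.frame with columns construction, urban_population,
#'   investment (>= 3 rows).
#' @return List with \code{urpopCoeff}, \code{investCoeff}, their standard
#'   errors (\code{se}, named), and \code{unidentifiable} (character vector
#'   of aliased terms, empty when all identified).
#' @export
fitSDCoefficients <- function(hist) {
  need <- c("construction", "urban_population", "investment")
  stopifnot(all(need %in% names(hist)))
  if (nrow(hist) < 3L)
    stop("need at least 3 years to identify two coefficients")
  fit <- stats::lm(construction ~ urban_population + investment, data = hist)
  cf <- stats::coef(fit)
  if (all(is.na(cf[-1])))
    stop("design is rank deficient; no coefficient identifiable")
  aliased <- names(cf)[-1][is.na(cf[-1])]
  if (length(aliased))
    warning("coefficient(s) not identifiable (collinear): ",
            paste(aliased, collapse = ", "), call. = FALSE)
  sm <- suppressWarnings(summary(fit))$coefficients  # noise-free fits are legitimate here
  se <- stats::setNames(rep(NA_real_, 2), c("urban_population", "investment"))
  for (nm in rownames(sm)) if (nm %in% names(se)) se[nm] <- sm[nm, "Std. Error"]
  list(urpopCoeff = unname(cf["urban_population"]),
       investCoeff = unname(cf["investment"]),
       se = se,
       unidentifiable = sub("^urban_population$", "urpopCoeff",
                            sub("^investment$", "investCoeff", aliased)))
}
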
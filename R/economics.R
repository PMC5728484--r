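#' @include AllClasses.R composition.R
NULL

#' Default unit management costs
#'
#' Statewide-average per-acre habitat management costs elicited from
#' wildlife managers: tree removal $650/acre and wetland restoration
#' $6250/acre.
#'
#' @param treeRemoval $/acre cost of removing trees.
#' @param wetlandRestoration $/acre cost of restoring wetland.
#' @return Named numeric vector with entries \code{tree_removal} and
#'   \code{wetland_restoration}.
#' @export
unitManagementCosts <- function(treeRemoval = 650,
                                wetlandRestoration = 6250) {
  if (treeRemoval < 0 || wetlandRestoration < 0)
    stop("unit management costs must be non-negative")
  c(tree_removal = as.numeric(treeRemoval),
    wetland_restoration = as.numeric(wetlandRestoration))
}

#' Convert a landcover composition to per-class acres
#'
#' The cost formulas are stated in acres while landscapes are described by
#' proportions; this converts via the township area using
#' 2.47105381 acres/hectare.
#'
#' @param composition A \code{\link{LandcoverComposition}} or named
#'   proportion vector.
#' @param townshipArea Landscape area in hectares (default 9324, a
#'   public-land-survey township).
#' @return Named numeric vector of acres per class, summing to the total
#'   township acreage.
#' @export
compositionToAcres <- function(composition, townshipArea = 9324) {
  composition <- asComposition(composition)
  if (!is.numeric(townshipArea) || townshipArea <= 0)
    stop("townshipArea must be a positive number of hectares")
  landcoverProportions(composition) * townshipArea * ACRES_PER_HECTARE
}

#' Annual collective gross income of a landscape
#'
#' Landowner revenue per year: crop acres x yield x price for row crop and
#' small grain, plus rangeland acres x pasture rental. CRP, trees, wetland
#' and "other" contribute nothing here — CRP rental is accounted
#' separately in \code{\link{agriculturalCost}} to avoid double counting.
#'
#' @param acres Named numeric vector of per-class acres (from
#'   \code{\link{compositionToAcres}}).
#' @param profile A \code{\link{CountyProfile}} supplying yields, prices
#'   and the pasture rental rate.
#' @return $/year (numeric scalar).
#' @export
grossIncome <- function(acres, profile) {
  stopifnot(is(profile, "CountyProfile"))
  missing <- setdiff(c("row_crop", "small_grain", "rangeland"), names(acres))
  if (length(missing) > 0L)
    stop(sprintf("acres vector is missing class(es): %s",
                 paste(missing, collapse = ", ")))
  if (any(acres < 0)) stop("acres must be non-negative")
  acres[["row_crop"]] * profile@cropYield[["row_crop"]] *
    profile@cropPrice[["row_crop"]] +
  acres[["small_grain"]] * profile@cropYield[["small_grain"]] *
    profile@cropPrice[["small_grain"]] +
  acres[["rangeland"]] * profile@pastureRental
}

#' Agricultural incentive cost of a scenario
#'
#' The incentive a manager must pay landowners to adopt the scenario:
#' the baseline-minus-scenario difference in annual collective gross
#' income multiplied by the horizon, plus the horizon-length cost of the
#' NEW CRP contracts the scenario creates
#' (\code{crp_rental x max(0, scenario CRP acres - baseline CRP acres) x
#' horizon}). Negative values mean the scenario is more profitable for
#' landowners than the baseline and are reported as-is.
#'
#' @param baselineAcres,scenarioAcres Named per-class acre vectors.
#' @param profile A \code{\link{CountyProfile}}.
#' @param horizon Contract horizon in years (default 10, a typical CRP
#'   contract length).
#' @param crpMode \code{"increment"} (default) charges rental on the CRP
#'   increase only; \code{"all"} charges rental on all scenario CRP acres.
#' @return $ over the horizon (numeric scalar).
#' @export
agriculturalCost <- function(baselineAcres, scenarioAcres, profile,
                             horizon = 10,
                             crpMode = c("increment", "all")) {
  stopifnot(is(profile, "CountyProfile"))
  crpMode <- match.arg(crpMode)
  if (horizon <= 0) stop("horizon must be positive")
  incomeDiff <- grossIncome(baselineAcres, profile) -
    grossIncome(scenarioAcres, profile)
  crpAcres <- switch(crpMode,
    increment = max(0, scenarioAcres[["crp"]] - baselineAcres[["crp"]]),
    all = scenarioAcres[["crp"]])
  incomeDiff * horizon + profile@crpRental * crpAcres * horizon
}

#' One-sided habitat management costs
#'
#' Tree removal is paid only when the scenario REDUCES tree acres (no cost
#' for gaining trees, no revenue from removal); wetland restoration is
#' paid only when the scenario INCREASES wetland acres (removing wetlands
#' costs the manager nothing).
#'
#' @param baselineAcres,scenarioAcres Named per-class acre vectors.
#' @param costs Unit costs from \code{\link{unitManagementCosts}}.
#' @return Named numeric vector \code{c(tree_cost, wetland_cost)}, both
#'   >= 0.
#' @export
managementCost <- function(baselineAcres, scenarioAcres,
                           costs = unitManagementCosts()) {
  if (any(c(baselineAcres, scenarioAcres) < 0))
    stop("acres must be non-negative")
  tree <- max(0, baselineAcres[["trees"]] - scenarioAcres[["trees"]]) *
    costs[["tree_removal"]]
  wetland <- max(0, scenarioAcres[["wetland"]] - baselineAcres[["wetland"]]) *
    costs[["wetland_restoration"]]
  c(tree_cost = tree, wetland_cost = wetland)
}

#' Total 10-year cost of converting baseline to scenario
#'
#' Sums the agricultural incentive cost and the one-sided tree and wetland
#' management costs into a \code{\link{CostBreakdown}}.
#'
#' @param baseline,scenario \code{\link{LandcoverComposition}}s (or named
#'   proportion vectors) describing the landscape before and after
#'   management.
#' @param profile A \code{\link{CountyProfile}}.
#' @param costs Unit costs from \code{\link{unitManagementCosts}}.
#' @param townshipArea Hectares (default 9324).
#' @param horizon Years (default 10).
#' @param crpMode See \code{\link{agriculturalCost}}.
#' @return A \code{\link{CostBreakdown}}.
#' @export
totalCost <- function(baseline, scenario, profile,
                      costs = unitManagementCosts(),
                      townshipArea = 9324, horizon = 10,
                      crpMode = c("increment", "all")) {
  stopifnot(is(profile, "CountyProfile"))
  crpMode <- match.arg(crpMode)
  ba <- compositionToAcres(baseline, townshipArea)
  sa <- compositionToAcres(scenario, townshipArea)
  ag <- agriculturalCost(ba, sa, profile, horizon, crpMode)
  mg <- managementCost(ba, sa, costs)
  new("CostBreakdown",
      agriculturalCost = ag,
      treeCost = mg[["tree_cost"]],
      wetlandCost = mg[["wetland_cost"]],
      total = ag + mg[["tree_cost"]] + mg[["wetland_cost"]],
      horizonYears = as.numeric(horizon),
      countyId = profile@countyId)
}

#' Serialise a cost breakdown to a JSON-ready list
#'
#' @param breakdown A \code{\link{CostBreakdown}}.
#' @return List mirroring the breakdown fields, suitable for
#'   \code{jsonlite::write_json(..., auto_unbox = TRUE)}.
#' @export
costAsList <- function(breakdown) {
  stopifnot(is(breakdown, "CostBreakdown"))
  list(agricultural_cost = breakdown@agriculturalCost,
       tree_cost = breakdown@treeCost,
       wetland_cost = breakdown@wetlandCost,
       total = breakdown@total,
       horizon_years = breakdown@horizonYears,
       county_id = breakdown@countyId)
}

#' Human-readable cost summary
#'
#' @param breakdown A \code{\link{CostBreakdown}}.
#' @return Character vector of summary lines (also usable with
#'   \code{writeLines}). A negative agricultural cost is flagged as a net
#'   gain to landowners.
#' @export
costSummaryText <- function(breakdown) {
  stopifnot(is(breakdown, "CostBreakdown"))
  fmt <- function(x) formatC(x, format = "f", digits = 2, big.mark = ",")
  lines <- c(
    sprintf("Management cost over %g years%s", breakdown@horizonYears,
            if (nzchar(breakdown@countyId))
              paste0(" (county ", breakdown@countyId, ")") else ""),
    sprintf("  Agricultural incentive cost: $%s%s",
            fmt(breakdown@agriculturalCost),
            if (breakdown@agriculturalCost < 0)
              "  [negative: scenario is a net gain to landowners]" else ""),
    sprintf("  Tree removal cost:           $%s", fmt(breakdown@treeCost)),
    sprintf("  Wetland restoration cost:    $%s", fmt(breakdown@wetlandCost)),
    sprintf("  Total cost:                  $%s", fmt(breakdown@total)))
  lines
}
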
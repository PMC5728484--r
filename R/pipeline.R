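#' @include AllClasses.R profiles.R landscape.R focal.R suitability.R
#'   economics.R io-raster.R
NULL

#' Summarise a suitability surface
#'
#' @param surface A \code{\link{SuitabilitySurface}} (categorised or not).
#' @return A one-row data.frame with \code{mean}, \code{min}, \code{max}
#'   and \code{n_pixels}, plus one \code{cat<k>} column per category when
#'   the surface is categorised.
#' @export
summarizeSurface <- function(surface) {
  stopifnot(is(surface, "SuitabilitySurface"))
  v <- surface@values
  out <- data.frame(mean = mean(v), min = min(v), max = max(v),
                    n_pixels = length(v))
  if (surface@nCategories > 0L) {
    cc <- categoryCounts(surface)
    out <- cbind(out, as.data.frame(as.list(cc)))
  }
  out
}

#' Resolve a run configuration
#'
#' Builds the fully resolved inputs of a scenario run from a configuration
#' list (typically parsed from YAML): the baseline composition (from a
#' county profile or given explicitly), the scenario composition (baseline
#' plus slider-style deltas), the coefficient set and the scale map.
#'
#' Recognised fields: \code{profiles} (CSV path) with \code{county_id},
#' OR \code{baseline} (named proportion mapping); \code{deltas} (named
#' mapping, optional); \code{coefficients} (YAML path, optional — the
#' labelled placeholder default is used if absent); \code{scale_map}
#' (named mapping, optional); \code{core_rows}, \code{core_cols},
#' \code{buffer_px}, \code{pixel_size}, \code{horizon}, \code{k_categories}
#' (optional scalars).
#'
#' @param config Named list.
#' @return List with elements \code{baseline}, \code{scenario},
#'   \code{profile} (may be NULL), \code{coefficients}, \code{scaleMap}
#'   and the grid/horizon scalars.
#' @export
resolveConfig <- function(config) {
  profile <- NULL
  if (!is.null(config$profiles)) {
    profiles <- loadProfiles(config$profiles)
    cid <- config$county_id
    if (is.null(cid))
      stop("config supplies 'profiles' but no 'county_id'")
    if (!cid %in% names(profiles))
      stop(sprintf("county '%s' not found in %s", cid, config$profiles))
    profile <- profiles[[cid]]
    baseline <- profile@meanComposition
  } else if (!is.null(config$baseline)) {
    baseline <- landcoverComposition(proportions = unlist(config$baseline))
  } else {
    stop("config must supply either 'profiles' + 'county_id' or 'baseline'")
  }
  scenario <- applyDeltas(baseline, unlist(config$deltas))
  coefficients <- if (!is.null(config$coefficients)) {
    readCoefficients(config$coefficients)
  } else defaultCoefficients()
  scaleMap <- if (!is.null(config$scale_map)) {
    sm <- unlist(config$scale_map)
    stats::setNames(as.integer(sm), names(sm))
  } else defaultScaleMap()
  list(baseline = baseline, scenario = scenario, profile = profile,
       coefficients = coefficients, scaleMap = scaleMap,
       coreRows = if (is.null(config$core_rows)) 84L
                  else as.integer(config$core_rows),
       coreCols = if (is.null(config$core_cols)) 111L
                  else as.integer(config$core_cols),
       bufferPx = if (is.null(config$buffer_px)) 50L
                  else as.integer(config$buffer_px),
       pixelSize = if (is.null(config$pixel_size)) 100
                   else as.numeric(config$pixel_size),
       horizon = if (is.null(config$horizon)) 10
                 else as.numeric(config$horizon),
       kCategories = if (is.null(config$k_categories)) 5L
                     else as.integer(config$k_categories))
}

#' Run a full management-scenario analysis
#'
#' The batch analogue of the interactive simulator: for BOTH the baseline
#' and the scenario composition it simulates a township raster (same seed,
#' so an identity scenario reproduces the baseline exactly), computes the
#' focal stack, predicts and categorises the suitability surface, and
#' prices the conversion with the economics module. All outputs are
#' written under \code{outDir}; identical config + seed give identical
#' outputs.
#'
#' @param config Named list (see \code{\link{resolveConfig}}) or a path to
#'   a YAML file holding one.
#' @param seed Integer seed for landscape realisation.
#' @param outDir Output directory (created if missing), or NULL to skip
#'   all file output.
#' @param costs Unit management costs (default
#'   \code{\link{unitManagementCosts}()}).
#' @return List with elements \code{baseline} and \code{scenario} (each
#'   holding \code{grid}, \code{stack}, \code{surface}, \code{summary}),
#'   \code{cost} (a \code{\link{CostBreakdown}}) and \code{seed}.
#' @export
runScenario <- function(config, seed = 1L, outDir = NULL,
                        costs = unitManagementCosts()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  rc <- resolveConfig(config)
  maxRadius <- max(rc$scaleMap)
  if (maxRadius > rc$bufferPx)
    stop(sprintf(
      "largest window radius (%d px) exceeds buffer (%d px); increase buffer_px",
      maxRadius, rc$bufferPx))

  analyse <- function(composition) {
    grid <- generateTownship(composition,
                             coreRows = rc$coreRows, coreCols = rc$coreCols,
                             bufferPx = rc$bufferPx,
                             pixelSize = rc$pixelSize, seed = seed)
    stack <- computeStack(grid, rc$scaleMap)
    surface <- categorizeSurface(predictSurface(stack, rc$coefficients),
                                 k = rc$kCategories)
    list(grid = grid, stack = stack, surface = surface,
         summary = summarizeSurface(surface))
  }
  base <- analyse(rc$baseline)
  scen <- analyse(rc$scenario)

  areaHa <- coreAreaHa(base$grid)
  cost <- if (!is.null(rc$profile)) {
    totalCost(rc$baseline, rc$scenario, rc$profile, costs = costs,
              townshipArea = areaHa, horizon = rc$horizon)
  } else NULL

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(outDir, ...)
    for (side in c("baseline", "scenario")) {
      res <- if (side == "baseline") base else scen
      writeTownshipRaster(res$grid, fp(paste0(side, "_landcover.asc")))
      writeAsciiGrid(suitabilityValues(res$surface),
                     fp(paste0(side, "_suitability.asc")),
                     cellSize = rc$pixelSize)
      writeAsciiGrid(suitabilityCategories(res$surface),
                     fp(paste0(side, "_categories.asc")),
                     cellSize = rc$pixelSize)
      utils::write.csv(res$summary, fp(paste0(side, "_summary.csv")),
                       row.names = FALSE)
    }
    if (!is.null(cost)) {
      jsonlite::write_json(costAsList(cost), fp("cost.json"),
                           auto_unbox = TRUE, digits = NA)
      writeLines(costSummaryText(cost), fp("cost_summary.txt"))
    }
    log <- c(
      sprintf("habscape run log"),
      sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      sprintf("package version: %s",
              as.character(utils::packageVersion("habscape"))),
      sprintf("R version: %s", R.version.string),
      sprintf("seed: %d", as.integer(seed)),
      sprintf("config md5: %s", {
        tf <- tempfile()
        on.exit(unlink(tf), add = TRUE)
        saveRDS(config, tf, version = 2)
        unname(tools::md5sum(tf))
      }),
      sprintf("core: %d x %d px; buffer %d px; pixel %g m",
              rc$coreRows, rc$coreCols, rc$bufferPx, rc$pixelSize),
      sprintf("core area: %.2f ha", areaHa),
      sprintf("horizon: %g years", rc$horizon),
      sprintf("scale map: %s",
              paste(sprintf("%s=%d", names(rc$scaleMap), rc$scaleMap),
                    collapse = " ")))
    writeLines(log, fp("run_log.txt"))
  }

  list(baseline = base, scenario = scen, cost = cost,
       seed = as.integer(seed))
}
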
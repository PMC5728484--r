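#' @import methods
NULL

#' Canonical landcover classes
#'
#' The seven landcover classes recognised throughout the package, in the
#' canonical order used for deterministic tie-breaking during pixel
#' apportionment. \code{"other"} is the residual class: it appears on
#' simulated landscapes but never enters the habitat model.
#'
#' @format Character vector of length 7.
#' @export
landcoverClasses <- c("crp", "row_crop", "small_grain", "rangeland",
                      "trees", "wetland", "other")

#' Model covariates
#'
#' The six landcover classes that act as covariates in the habitat
#' suitability model (all classes except the residual \code{"other"}).
#'
#' @format Character vector of length 6.
#' @export
modelCovariates <- setdiff(landcoverClasses, "other")

## acres per hectare; fixed US survey conversion used for all cost arithmetic
ACRES_PER_HECTARE <- 2.47105381

#' LandcoverComposition: proportions of landcover classes on a landscape
#'
#' A named vector of area proportions over the seven canonical landcover
#' classes. Proportions lie in [0, 1] and sum to 1; \code{"other"} is the
#' residual class and may be filled in automatically by the constructor.
#'
#' @slot proportions Named numeric vector over \code{\link{landcoverClasses}}.
#' @seealso \code{\link{landcoverComposition}}
#' @export
setClass("LandcoverComposition",
         representation(proportions = "numeric"))

setValidity("LandcoverComposition", function(object) {
  p <- object@proportions
  if (!identical(names(p), landcoverClasses))
    return(sprintf("proportions must be named exactly: %s",
                   paste(landcoverClasses, collapse = ", ")))
  if (anyNA(p) || any(!is.finite(p)))
    return("proportions must be finite and non-missing")
  if (any(p < 0) || any(p > 1)) {
    bad <- names(p)[p < 0 | p > 1]
    return(sprintf("proportion out of [0, 1] for class(es): %s",
                   paste(bad, collapse = ", ")))
  }
  if (abs(sum(p) - 1) > 1e-9)
    return(sprintf("proportions must sum to 1 (got %.12f)", sum(p)))
  TRUE
})

#' CountyProfile: default composition and economics for one county
#'
#' Bundles a county's mean township landcover composition with the
#' NASS-style economic parameters needed to price management scenarios:
#' crop yields (bushels/acre), crop prices ($/bushel), the pasture rental
#' rate and the CRP rental rate (both $/acre/year).
#'
#' @slot countyId Character scalar identifier.
#' @slot meanComposition A \code{\link{LandcoverComposition}}.
#' @slot cropYield Named numeric, bushels/acre for \code{row_crop} and
#'   \code{small_grain}.
#' @slot cropPrice Named numeric, $/bushel for the same two classes.
#' @slot pastureRental Numeric scalar, $/acre/year for rangeland.
#' @slot crpRental Numeric scalar, $/acre/year paid on CRP contracts.
#' @export
setClass("CountyProfile",
         representation(countyId = "character",
                        meanComposition = "LandcoverComposition",
                        cropYield = "numeric",
                        cropPrice = "numeric",
                        pastureRental = "numeric",
                        crpRental = "numeric"))

setValidity("CountyProfile", function(object) {
  crops <- c("row_crop", "small_grain")
  if (length(object@countyId) != 1L || is.na(object@countyId))
    return("countyId must be a single non-missing string")
  if (!identical(names(object@cropYield), crops) ||
      !identical(names(object@cropPrice), crops))
    return("cropYield and cropPrice must be named row_crop, small_grain")
  econ <- c(object@cropYield, object@cropPrice,
            object@pastureRental, object@crpRental)
  if (anyNA(econ) || any(econ < 0))
    return("economic values must be non-negative and non-missing")
  TRUE
})

#' TownshipGrid: buffered categorical landcover raster
#'
#' A realised township landscape: a core analysis extent surrounded by a
#' buffer wide enough that every downstream moving window lies fully on
#' data. Labels are integer class codes indexing
#' \code{\link{landcoverClasses}}; per-class pixel counts over the full
#' grid (core + buffer) equal the largest-remainder quantization of the
#' generating composition.
#'
#' @slot labels Integer matrix (rows x cols over the full buffered extent)
#'   of class codes, 1-based into \code{landcoverClasses}.
#' @slot coreRows,coreCols Integer core extent in pixels.
#' @slot bufferPx Integer buffer width in pixels (default 50).
#' @slot pixelSize Numeric pixel edge length in meters (default 100).
#' @slot composition The generating \code{\link{LandcoverComposition}}.
#' @slot seed Integer seed used for spatial placement.
#' @seealso \code{\link{generateTownship}}
#' @export
setClass("TownshipGrid",
         representation(labels = "matrix",
                        coreRows = "integer",
                        coreCols = "integer",
                        bufferPx = "integer",
                        pixelSize = "numeric",
                        composition = "LandcoverComposition",
                        seed = "integer"))

setValidity("TownshipGrid", function(object) {
  nr <- object@coreRows + 2L * object@bufferPx
  nc <- object@coreCols + 2L * object@bufferPx
  if (!identical(dim(object@labels), c(nr, nc)))
    return(sprintf("label grid is %d x %d but core + buffer implies %d x %d",
                   nrow(object@labels), ncol(object@labels), nr, nc))
  if (object@coreRows < 1L || object@coreCols < 1L)
    return("core dimensions must be >= 1 pixel")
  if (object@bufferPx < 0L) return("bufferPx must be >= 0")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  lab <- object@labels
  if (any(lab < 1L | lab > length(landcoverClasses)))
    return("labels must be codes 1..7 into landcoverClasses")
  counts <- tabulate(lab, nbins = length(landcoverClasses))
  expected <- quantizeComposition(object@composition, length(lab))
  if (!identical(as.integer(counts), as.integer(expected)))
    return("per-class pixel counts do not match quantized composition")
  TRUE
})

#' CircularKernel: membership mask for a circular moving window
#'
#' The set of integer lattice offsets (dx, dy) with Euclidean
#' center-to-center distance at most \code{radiusPx}; boundary included.
#' A radius-10 kernel covers 317 cells.
#'
#' @slot radiusPx Integer radius in pixels.
#' @slot mask Logical (2r+1) x (2r+1) membership matrix.
#' @slot cellCount Integer number of member cells.
#' @seealso \code{\link{buildKernel}}
#' @export
setClass("CircularKernel",
         representation(radiusPx = "integer",
                        mask = "matrix",
                        cellCount = "integer"))

setValidity("CircularKernel", function(object) {
  r <- object@radiusPx
  if (r < 0L) return("radiusPx must be >= 0")
  if (!identical(dim(object@mask), c(2L * r + 1L, 2L * r + 1L)))
    return("mask must be (2r+1) x (2r+1)")
  off <- seq(-r, r)
  d2 <- outer(off^2, off^2, `+`)
  if (!identical(object@mask, d2 <= r^2))
    return("mask does not match Euclidean distance <= radius rule")
  if (object@cellCount != sum(object@mask))
    return("cellCount does not match mask")
  TRUE
})

#' FocalProportionStack: windowed landcover proportions per covariate
#'
#' One core-extent layer per model covariate holding the proportion of
#' that landcover class within the covariate's circular window around each
#' core pixel. The residual class \code{"other"} has no layer.
#'
#' @slot layers Named list of numeric matrices (core extent), one per
#'   covariate in \code{\link{modelCovariates}}.
#' @slot radii Named integer vector: window radius (pixels) per covariate.
#' @seealso \code{\link{computeStack}}
#' @export
setClass("FocalProportionStack",
         representation(layers = "list",
                        radii = "integer"))

setValidity("FocalProportionStack", function(object) {
  if (!setequal(names(object@layers), modelCovariates))
    return("layers must cover exactly the six model covariates")
  if (!setequal(names(object@radii), modelCovariates))
    return("radii must cover exactly the six model covariates")
  dims <- unique(lapply(object@layers, dim))
  if (length(dims) != 1L)
    return("all layers must share the core extent")
  rng <- range(unlist(object@layers, use.names = FALSE))
  if (rng[1] < 0 || rng[2] > 1)
    return("focal proportions must lie in [0, 1]")
  TRUE
})

#' CoefficientSet: parameters of the habitat suitability equation
#'
#' The intercept and the ten slope coefficients of the log-linear habitat
#' model: linear terms for rangeland, CRP, trees and wetland, and linear,
#' quadratic and cubic terms for row crop and small grain. All on the log
#' scale per unit focal proportion, applied to un-centered,
#' un-standardized proportions.
#'
#' @slot intercept Numeric scalar (default 3.07).
#' @slot slopes Named numeric vector with names
#'   \code{rangeland, crp, row_crop, row_crop2, row_crop3, small_grain,
#'   small_grain2, small_grain3, trees, wetland}.
#' @seealso \code{\link{coefficientSet}}, \code{\link{defaultCoefficients}}
#' @export
setClass("CoefficientSet",
         representation(intercept = "numeric",
                        slopes = "numeric"))

#' Slope term names of the suitability equation
#' @noRd
slopeNames <- c("rangeland", "crp",
                "row_crop", "row_crop2", "row_crop3",
                "small_grain", "small_grain2", "small_grain3",
                "trees", "wetland")

setValidity("CoefficientSet", function(object) {
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    return("intercept must be a single finite number")
  if (!identical(names(object@slopes), slopeNames))
    return(sprintf("slopes must be named exactly: %s",
                   paste(slopeNames, collapse = ", ")))
  if (any(!is.finite(object@slopes)))
    return("all slopes must be finite")
  TRUE
})

#' SuitabilitySurface: predicted relative habitat suitability
#'
#' The exponentiated linear predictor of the habitat model at every core
#' pixel (strictly positive), optionally classified into ordinal
#' relative-suitability categories.
#'
#' @slot values Numeric matrix (core extent) of positive suitability values.
#' @slot categories Integer matrix of ordinal category codes, or a 0 x 0
#'   matrix until \code{\link{categorizeSurface}} is called.
#' @slot nCategories Integer number of categories (0 if uncategorised).
#' @export
setClass("SuitabilitySurface",
         representation(values = "matrix",
                        categories = "matrix",
                        nCategories = "integer"))

setValidity("SuitabilitySurface", function(object) {
  if (any(!is.finite(object@values)) || any(object@values <= 0))
    return("suitability values must be finite and strictly positive")
  if (length(object@categories) > 0L) {
    if (!identical(dim(object@categories), dim(object@values)))
      return("categories must match the values extent")
    o <- order(object@values)
    if (is.unsorted(object@categories[o]))
      return("category order must respect value order")
  }
  TRUE
})

#' CostBreakdown: 10-year cost of a management scenario
#'
#' The agricultural incentive cost (gross-income difference over the
#' horizon plus new CRP contract rentals), the one-sided tree-removal and
#' wetland-restoration costs, and their total, all in dollars over the
#' scenario horizon.
#'
#' @slot agriculturalCost Numeric $, may be negative if the scenario is
#'   more profitable than the baseline.
#' @slot treeCost Numeric $ >= 0.
#' @slot wetlandCost Numeric $ >= 0.
#' @slot total Numeric $, always the sum of the three components.
#' @slot horizonYears Numeric scenario horizon (default 10).
#' @slot countyId Character county identifier ("" if none).
#' @export
setClass("CostBreakdown",
         representation(agriculturalCost = "numeric",
                        treeCost = "numeric",
                        wetlandCost = "numeric",
                        total = "numeric",
                        horizonYears = "numeric",
                        countyId = "character"))

setValidity("CostBreakdown", function(object) {
  if (object@treeCost < 0 || object@wetlandCost < 0)
    return("tree and wetland costs must be non-negative")
  s <- object@agriculturalCost + object@treeCost + object@wetlandCost
  if (abs(object@total - s) > 1e-6 * max(1, abs(s)))
    return("total must equal the sum of its components")
  if (object@horizonYears <= 0) return("horizonYears must be positive")
  TRUE
})
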
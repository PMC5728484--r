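#' @include AllClasses.R
NULL

#' Extract landcover proportions
#'
#' @param x A \code{LandcoverComposition} or an object that carries one
#'   (a \code{CountyProfile} or \code{TownshipGrid}).
#' @return Named numeric vector over \code{\link{landcoverClasses}}.
#' @export
setGeneric("landcoverProportions", function(x) standardGeneric("landcoverProportions"))

#' @rdname landcoverProportions
#' @export
setMethod("landcoverProportions", "LandcoverComposition", function(x) x@proportions)

#' @rdname landcoverProportions
#' @export
setMethod("landcoverProportions", "CountyProfile",
          function(x) x@meanComposition@proportions)

#' @rdname landcoverProportions
#' @export
setMethod("landcoverProportions", "TownshipGrid",
          function(x) x@composition@proportions)

#' Suitability values of a surface
#' @param x A \code{SuitabilitySurface}.
#' @return Numeric matrix of per-pixel relative suitability.
#' @export
setGeneric("suitabilityValues", function(x) standardGeneric("suitabilityValues"))

#' @rdname suitabilityValues
#' @export
setMethod("suitabilityValues", "SuitabilitySurface", function(x) x@values)

#' Category codes of a categorised surface
#' @param x A \code{SuitabilitySurface}.
#' @return Integer matrix of ordinal categories, or NULL if uncategorised.
#' @export
setGeneric("suitabilityCategories",
           function(x) standardGeneric("suitabilityCategories"))

#' @rdname suitabilityCategories
#' @export
setMethod("suitabilityCategories", "SuitabilitySurface", function(x) {
  if (length(x@categories) == 0L) NULL else x@categories
})

#' Label matrix of a township grid
#'
#' @param x A \code{TownshipGrid}.
#' @param core Logical; if TRUE return only the core extent (buffer
#'   stripped), otherwise the full buffered grid.
#' @return Integer matrix of class codes into \code{landcoverClasses}.
#' @export
setGeneric("gridLabels", function(x, core = FALSE) standardGeneric("gridLabels"))

#' @rdname gridLabels
#' @export
setMethod("gridLabels", "TownshipGrid", function(x, core = FALSE) {
  if (!core) return(x@labels)
  b <- x@bufferPx
  x@labels[seq_len(x@coreRows) + b, seq_len(x@coreCols) + b, drop = FALSE]
})

#' Core area of a township grid in hectares
#' @param x A \code{TownshipGrid}.
#' @return Numeric scalar, hectares.
#' @export
setGeneric("coreAreaHa", function(x) standardGeneric("coreAreaHa"))

#' @rdname coreAreaHa
#' @export
setMethod("coreAreaHa", "TownshipGrid", function(x) {
  as.numeric(x@coreRows) * x@coreCols * x@pixelSize^2 / 1e4
})

setMethod("show", "LandcoverComposition", function(object) {
  cat("LandcoverComposition\n")
  p <- object@proportions
  cat(paste(sprintf("  %-12s %6.3f", names(p), p), collapse = "\n"), "\n")
})

setMethod("show", "CountyProfile", function(object) {
  cat("CountyProfile:", object@countyId, "\n")
  p <- landcoverProportions(object)
  cat("  composition:",
      paste(sprintf("%s=%.3f", names(p), p), collapse = " "), "\n")
  cat(sprintf("  row_crop %g bu/ac @ $%g/bu; small_grain %g bu/ac @ $%g/bu\n",
              object@cropYield["row_crop"], object@cropPrice["row_crop"],
              object@cropYield["small_grain"], object@cropPrice["small_grain"]))
  cat(sprintf("  pasture rental $%g/ac/yr; CRP rental $%g/ac/yr\n",
              object@pastureRental, object@crpRental))
})

setMethod("show", "TownshipGrid", function(object) {
  cat(sprintf("TownshipGrid: %d x %d core + %d px buffer (%g m pixels)\n",
              object@coreRows, object@coreCols, object@bufferPx,
              object@pixelSize))
  cat(sprintf("  core area %.0f ha; seed %d\n",
              coreAreaHa(object), object@seed))
})

setMethod("show", "CircularKernel", function(object) {
  cat(sprintf("CircularKernel: radius %d px, %d cells\n",
              object@radiusPx, object@cellCount))
})

setMethod("show", "FocalProportionStack", function(object) {
  d <- dim(object@layers[[1]])
  cat(sprintf("FocalProportionStack: %d layers on %d x %d core extent\n",
              length(object@layers), d[1], d[2]))
  r <- object@radii[modelCovariates]
  cat(paste(sprintf("  %-12s radius %2d px", names(r), r), collapse = "\n"),
      "\n")
})

setMethod("show", "CoefficientSet", function(object) {
  cat(sprintf("CoefficientSet: intercept %.4g\n", object@intercept))
  s <- object@slopes
  cat(paste(sprintf("  %-14s %8.4g", names(s), s), collapse = "\n"), "\n")
})

setMethod("show", "SuitabilitySurface", function(object) {
  v <- object@values
  cat(sprintf("SuitabilitySurface: %d x %d pixels, values %.4g .. %.4g\n",
              nrow(v), ncol(v), min(v), max(v)))
  if (object@nCategories > 0L)
    cat(sprintf("  categorised into %d ordinal classes\n",
                object@nCategories))
})

setMethod("show", "CostBreakdown", function(object) {
  cat(sprintf("CostBreakdown (%g-year horizon%s)\n", object@horizonYears,
              if (nzchar(object@countyId))
                paste0(", county ", object@countyId) else ""))
  cat(sprintf("  agricultural incentive: $%s\n",
              format(object@agriculturalCost, big.mark = ",")))
  cat(sprintf("  tree removal:           $%s\n",
              format(object@treeCost, big.mark = ",")))
  cat(sprintf("  wetland restoration:    $%s\n",
              format(object@wetlandCost, big.mark = ",")))
  cat(sprintf("  total:                  $%s\n",
              format(object@total, big.mark = ",")))
})
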
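#' @include AllClasses.R landscape.R
NULL

#' Build a circular moving-window kernel
#'
#' Membership rule: an offset (dx, dy) belongs to the window iff its
#' center-to-center Euclidean distance satisfies
#' \code{sqrt(dx^2 + dy^2) <= radiusPx} (boundary included). Under this
#' rule a radius-1 kernel has 5 cells and a radius-10 kernel 317 cells.
#'
#' @param radiusPx Window radius in pixels (>= 0).
#' @return A \code{\link{CircularKernel}}.
#' @export
buildKernel <- function(radiusPx) {
  r <- asCount(radiusPx, "radiusPx", allow_zero = TRUE)
  off <- seq(-r, r)
  mask <- outer(off^2, off^2, `+`) <= r^2
  new("CircularKernel", radiusPx = r, mask = mask,
      cellCount = as.integer(sum(mask)))
}

## Exact window counts of a 0/1 indicator over all core pixels.
## For each row offset dy the circular window covers the contiguous column
## run [-w, w] with w = floor(sqrt(r^2 - dy^2)); summing per-row column
## cumulative sums over these runs gives integer counts with no floating
## error, and one division at the very end yields the proportions.
windowCounts <- function(indicator, radius, coreRowsIdx, coreColsIdx) {
  S <- t(apply(indicator, 1L, cumsum))
  S0 <- cbind(0, S)  # S0[, j + 1] = sum of columns 1..j
  counts <- matrix(0, length(coreRowsIdx), length(coreColsIdx))
  for (dy in seq(-radius, radius)) {
    w <- floor(sqrt(radius^2 - dy^2))
    rows <- coreRowsIdx + dy
    counts <- counts +
      S0[rows, coreColsIdx + w + 1L, drop = FALSE] -
      S0[rows, coreColsIdx - w, drop = FALSE]
  }
  counts
}

#' Focal proportion of one landcover class
#'
#' Computes, for every core pixel, the proportion of the kernel's cells
#' occupied by the given class. The buffer guarantees every window lies
#' fully on data, so no edge correction is applied (or needed); counts
#' are accumulated in exact integer arithmetic and divided by the kernel
#' cell count once at the end.
#'
#' @param grid A \code{\link{TownshipGrid}}.
#' @param class A landcover class name (one of
#'   \code{\link{landcoverClasses}}).
#' @param kernel A \code{\link{CircularKernel}} with radius at most the
#'   grid's buffer width.
#' @return Numeric matrix (core extent) of fractions in [0, 1].
#' @export
focalProportion <- function(grid, class, kernel) {
  stopifnot(is(grid, "TownshipGrid"), is(kernel, "CircularKernel"))
  if (!class %in% landcoverClasses)
    stop(sprintf("unknown landcover class '%s'", class))
  r <- kernel@radiusPx
  b <- grid@bufferPx
  if (r > b)
    stop(sprintf(
      "kernel radius (%d px) exceeds grid buffer (%d px): every core window must lie fully on the grid",
      r, b))
  code <- match(class, landcoverClasses)
  indicator <- (grid@labels == code) * 1L
  ri <- seq_len(grid@coreRows) + b
  ci <- seq_len(grid@coreCols) + b
  windowCounts(indicator, r, ri, ci) / kernel@cellCount
}

#' Default covariate-to-radius scale map
#'
#' The habitat model evaluates each landcover covariate at the spatial
#' scale (1 km = 10 pixels or 5 km = 50 pixels) at which that covariate
#' best predicts pheasant abundance. The published source of the model
#' does not list which covariate takes which radius, so this shipped
#' default — crop classes and rangeland at 5 km; CRP, trees and wetland at
#' 1 km — is an ASSUMPTION and should be overridden when the true mapping
#' is known.
#'
#' @return Named integer vector over \code{\link{modelCovariates}} with
#'   values in \{10, 50\}.
#' @export
defaultScaleMap <- function() {
  c(crp = 10L, row_crop = 50L, small_grain = 50L,
    rangeland = 50L, trees = 10L, wetland = 10L)
}

#' Compute the focal proportion stack for the habitat model
#'
#' One layer per model covariate, each the focal proportion of that class
#' at its mapped window radius. The residual class \code{"other"} is
#' excluded by construction: it is not a predictor of the species' abundance.
#'
#' @param grid A \code{\link{TownshipGrid}}.
#' @param scaleMap Named vector mapping every covariate in
#'   \code{\link{modelCovariates}} to a radius in pixels; all radii must
#'   be at most the grid's buffer width. Default
#'   \code{\link{defaultScaleMap}()}.
#' @param allowedRadii Radii permitted in \code{scaleMap}; defaults to the
#'   configured two analysis scales, 10 and 50 pixels.
#' @return A \code{\link{FocalProportionStack}}.
#' @export
computeStack <- function(grid, scaleMap = defaultScaleMap(),
                         allowedRadii = c(10L, 50L)) {
  stopifnot(is(grid, "TownshipGrid"))
  missing <- setdiff(modelCovariates, names(scaleMap))
  if (length(missing) > 0L)
    stop(sprintf("scaleMap is missing covariate(s): %s",
                 paste(missing, collapse = ", ")))
  scaleMap <- scaleMap[modelCovariates]
  if (!all(scaleMap %in% allowedRadii))
    stop(sprintf("scaleMap radii must be among {%s}",
                 paste(allowedRadii, collapse = ", ")))
  kernels <- lapply(unique(scaleMap), buildKernel)
  names(kernels) <- as.character(unique(scaleMap))
  layers <- lapply(modelCovariates, function(cl) {
    focalProportion(grid, cl, kernels[[as.character(scaleMap[[cl]])]])
  })
  names(layers) <- modelCovariates
  new("FocalProportionStack", layers = layers,
      radii = stats::setNames(as.integer(scaleMap), modelCovariates))
}
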
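#' @include AllClasses.R composition.R utils.R
NULL

#' Apportion pixels to landcover classes (largest remainder)
#'
#' Converts class proportions to integer pixel counts that sum exactly to
#' \code{nPixels}, using largest-remainder (Hamilton) apportionment:
#' each class receives the floor of its exact quota
#' \code{proportion * nPixels}, and the leftover pixels go to the classes
#' with the largest fractional remainders. Remainder ties are broken by
#' the canonical class order \code{\link{landcoverClasses}}, so the result
#' is fully deterministic and each count is within 1 pixel of its quota.
#'
#' @param composition A \code{\link{LandcoverComposition}} or named
#'   proportion vector.
#' @param nPixels Total pixels to apportion (>= 1).
#' @return Named integer vector over \code{landcoverClasses} summing to
#'   \code{nPixels}.
#' @examples
#' quantizeComposition(landcoverComposition(row_crop = 0.25, crp = 0.01),
#'                     9324)
#' @export
quantizeComposition <- function(composition, nPixels) {
  composition <- asComposition(composition)
  nPixels <- asCount(nPixels, "nPixels")
  p <- landcoverProportions(composition)
  quota <- p * nPixels
  counts <- floor(quota)
  leftover <- nPixels - sum(counts)
  if (leftover > 0) {
    rem <- quota - counts
    # order(): ties fall back to position, i.e. canonical class order
    take <- order(rem, decreasing = TRUE)[seq_len(leftover)]
    counts[take] <- counts[take] + 1
  }
  stats::setNames(as.integer(counts), landcoverClasses)
}

#' Simulate a buffered township landscape
#'
#' Realises a landcover composition as a categorical raster covering a
#' core "township" extent plus a buffer, by assigning class labels to
#' pixels proportionally (largest-remainder counts over the FULL buffered
#' grid) and placing them spatially at random: a seeded uniform random
#' permutation of pixel positions. Buffer pixels are drawn from the same
#' proportional assignment as the core, so moving windows centred on core
#' pixels see an unbiased landscape with no edge effects.
#'
#' The defaults give an 84 x 111 pixel core of 100 m pixels — exactly
#' 9324 one-hectare pixels, the 9324 ha area of a public-land-survey
#' township — inside a 50-pixel buffer, wide enough for the largest
#' (5 km = 50 pixel) analysis window.
#'
#' @param composition A \code{\link{LandcoverComposition}} or named
#'   proportion vector.
#' @param coreRows,coreCols Core extent in pixels.
#' @param bufferPx Buffer width in pixels.
#' @param pixelSize Pixel edge length in meters.
#' @param seed Integer seed controlling spatial placement. Identical
#'   inputs and seed give bit-identical grids; changing the seed changes
#'   placement but never the per-class pixel counts.
#' @return A \code{\link{TownshipGrid}}.
#' @export
generateTownship <- function(composition,
                             coreRows = 84L, coreCols = 111L,
                             bufferPx = 50L, pixelSize = 100,
                             seed = 1L) {
  composition <- asComposition(composition)
  coreRows <- asCount(coreRows, "coreRows")
  coreCols <- asCount(coreCols, "coreCols")
  bufferPx <- asCount(bufferPx, "bufferPx", allow_zero = TRUE)
  if (!is.numeric(pixelSize) || length(pixelSize) != 1L || pixelSize <= 0)
    stop("pixelSize must be a single positive number of meters")
  nr <- coreRows + 2L * bufferPx
  nc <- coreCols + 2L * bufferPx
  total <- nr * nc
  counts <- quantizeComposition(composition, total)
  pool <- rep.int(seq_along(landcoverClasses), counts)
  labels <- withSeed(seed, {
    perm <- sample.int(total)  # Fisher-Yates permutation of pixel indices
    out <- integer(total)
    out[perm] <- pool
    out
  })
  new("TownshipGrid",
      labels = matrix(labels, nrow = nr, ncol = nc),
      coreRows = coreRows, coreCols = coreCols,
      bufferPx = bufferPx, pixelSize = as.numeric(pixelSize),
      composition = composition,
      seed = asCount(seed, "seed", allow_zero = TRUE, allow_negative = TRUE))
}

#' Per-class pixel counts of a township grid
#'
#' @param grid A \code{\link{TownshipGrid}}.
#' @param core Logical; count over the core extent only (default: full
#'   buffered grid, where counts equal the quantized composition exactly).
#' @return Named integer vector over \code{\link{landcoverClasses}}.
#' @export
classCounts <- function(grid, core = FALSE) {
  stopifnot(is(grid, "TownshipGrid"))
  lab <- gridLabels(grid, core = core)
  stats::setNames(tabulate(lab, nbins = length(landcoverClasses)),
                  landcoverClasses)
}
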
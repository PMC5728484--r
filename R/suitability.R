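#' @include AllClasses.R focal.R
NULL

#' Construct a coefficient set for the suitability equation
#'
#' @param intercept Intercept on the log scale (default 3.07, the
#'   published value for the corrected pheasant-habitat model).
#' @param slopes Named numeric vector of the ten slope coefficients:
#'   \code{rangeland, crp, row_crop, row_crop2, row_crop3, small_grain,
#'   small_grain2, small_grain3, trees, wetland}. Terms with a numeric
#'   suffix are the quadratic and cubic powers of the SAME focal
#'   proportion, not separate layers.
#' @return A \code{\link{CoefficientSet}}.
#' @export
coefficientSet <- function(intercept = 3.07, slopes) {
  if (is.null(names(slopes)))
    stop("slopes must be a named vector")
  missing <- setdiff(slopeNames, names(slopes))
  if (length(missing) > 0L)
    stop(sprintf("missing slope coefficient(s): %s",
                 paste(missing, collapse = ", ")))
  extra <- setdiff(names(slopes), slopeNames)
  if (length(extra) > 0L)
    stop(sprintf("unknown slope coefficient(s): %s",
                 paste(extra, collapse = ", ")))
  new("CoefficientSet", intercept = as.numeric(intercept),
      slopes = as.numeric(slopes)[match(slopeNames, names(slopes))] |>
        stats::setNames(slopeNames))
}

#' Default (placeholder) coefficient configuration
#'
#' The intercept is the published 3.07; the ten slopes are PLACEHOLDERS
#' chosen only for sign plausibility (grass and wetland positive, trees
#' negative, hump-shaped crop responses), because the fitted slope values
#' were published elsewhere and are not reproduced here. Every analysis
#' intended to say something about a real landscape must supply its own
#' slopes, e.g. via \code{\link{readCoefficients}}.
#'
#' @return A \code{\link{CoefficientSet}}.
#' @export
defaultCoefficients <- function() {
  coefficientSet(
    intercept = 3.07,
    slopes = c(rangeland = 1.5, crp = 2.0,
               row_crop = 4.0, row_crop2 = -6.0, row_crop3 = 1.5,
               small_grain = 1.0, small_grain2 = -1.0, small_grain3 = 0.2,
               trees = -4.0, wetland = 2.0))
}

#' Read a coefficient set from a YAML file
#'
#' Expected structure: a top-level \code{intercept} scalar and a
#' \code{slopes} mapping with the ten term names used by
#' \code{\link{coefficientSet}}.
#'
#' @param path Path to a YAML file.
#' @return A \code{\link{CoefficientSet}}.
#' @export
readCoefficients <- function(path) {
  if (!file.exists(path))
    stop(sprintf("coefficient file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$intercept) || is.null(cfg$slopes))
    stop("coefficient file must contain 'intercept' and 'slopes'")
  coefficientSet(intercept = cfg$intercept, slopes = unlist(cfg$slopes))
}

#' Write a coefficient set to a YAML file
#' @param coefficients A \code{\link{CoefficientSet}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCoefficients <- function(coefficients, path) {
  stopifnot(is(coefficients, "CoefficientSet"))
  yaml::write_yaml(list(intercept = coefficients@intercept,
                        slopes = as.list(coefficients@slopes)), path)
  invisible(path)
}

#' Linear predictor of the habitat model at one pixel
#'
#' Evaluates the log-scale linear predictor
#' \deqn{\eta = \beta_0 + \alpha_R R + \alpha_C C + \alpha_{RC} RC +
#'   \alpha_{RC2} RC^2 + \alpha_{RC3} RC^3 + \alpha_G G + \alpha_{G2} G^2 +
#'   \alpha_{G3} G^3 + \alpha_T T + \alpha_W W}
#' from a pixel's focal covariate fractions (un-centered and
#' un-standardized). The quadratic and cubic crop terms are powers of the
#' same focal value.
#'
#' @param focalValues Named numeric vector over
#'   \code{\link{modelCovariates}}, each in [0, 1].
#' @param coefficients A \code{\link{CoefficientSet}}.
#' @return Log relative suitability (numeric scalar).
#' @examples
#' eta <- linearPredictor(
#'   setNames(numeric(6), modelCovariates), defaultCoefficients())
#' # eta == 3.07: the intercept alone
#' @export
linearPredictor <- function(focalValues, coefficients) {
  stopifnot(is(coefficients, "CoefficientSet"))
  missing <- setdiff(modelCovariates, names(focalValues))
  if (length(missing) > 0L)
    stop(sprintf("focalValues is missing covariate(s): %s",
                 paste(missing, collapse = ", ")))
  v <- as.numeric(focalValues[modelCovariates])
  if (anyNA(v) || any(v < 0 | v > 1))
    stop("focal covariate fractions must lie in [0, 1]")
  names(v) <- modelCovariates
  a <- coefficients@slopes
  coefficients@intercept +
    a[["rangeland"]] * v[["rangeland"]] +
    a[["crp"]] * v[["crp"]] +
    a[["row_crop"]] * v[["row_crop"]] +
    a[["row_crop2"]] * v[["row_crop"]]^2 +
    a[["row_crop3"]] * v[["row_crop"]]^3 +
    a[["small_grain"]] * v[["small_grain"]] +
    a[["small_grain2"]] * v[["small_grain"]]^2 +
    a[["small_grain3"]] * v[["small_grain"]]^3 +
    a[["trees"]] * v[["trees"]] +
    a[["wetland"]] * v[["wetland"]]
}

#' Predict the relative habitat suitability surface
#'
#' Applies the exponentiated linear predictor at every core pixel:
#' \code{value[p] = exp(eta[p])}. Values are relative abundance-scale
#' indices under an assumed constant detection probability — comparable
#' across pixels, not absolute counts. Predictions use the supplied mean
#' coefficient values only; no uncertainty is propagated.
#'
#' @param stack A \code{\link{FocalProportionStack}}.
#' @param coefficients A \code{\link{CoefficientSet}}.
#' @return A \code{\link{SuitabilitySurface}} (uncategorised).
#' @export
predictSurface <- function(stack, coefficients) {
  stopifnot(is(stack, "FocalProportionStack"),
            is(coefficients, "CoefficientSet"))
  L <- stack@layers
  a <- coefficients@slopes
  eta <- coefficients@intercept +
    a[["rangeland"]] * L$rangeland +
    a[["crp"]] * L$crp +
    a[["row_crop"]] * L$row_crop +
    a[["row_crop2"]] * L$row_crop^2 +
    a[["row_crop3"]] * L$row_crop^3 +
    a[["small_grain"]] * L$small_grain +
    a[["small_grain2"]] * L$small_grain^2 +
    a[["small_grain3"]] * L$small_grain^3 +
    a[["trees"]] * L$trees +
    a[["wetland"]] * L$wetland
  values <- exp(eta)
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values))[1]
    stop(sprintf(
      "non-finite suitability at pixel [%d, %d] (linear predictor %g)",
      row(values)[bad], col(values)[bad], eta[bad]))
  }
  new("SuitabilitySurface", values = values,
      categories = matrix(integer(0), 0, 0), nCategories = 0L)
}

#' Classify a suitability surface into ordinal categories
#'
#' Either cuts at explicit strictly increasing value thresholds, or (the
#' default) forms \code{k} equal-count (quantile) categories of the
#' current surface: scale-free relative-suitability classes from lowest
#' (1) to highest (k). Tied values always share a category, so category
#' order respects value order.
#'
#' @param surface A \code{\link{SuitabilitySurface}}.
#' @param breaks Strictly increasing numeric thresholds; a value v falls
#'   in category \code{sum(v > breaks) + 1}. Mutually exclusive with
#'   \code{k}.
#' @param k Number of equal-count categories (>= 2; default 5).
#' @return The surface with \code{categories} populated.
#' @export
categorizeSurface <- function(surface, breaks = NULL, k = 5L) {
  stopifnot(is(surface, "SuitabilitySurface"))
  v <- surface@values
  if (!is.null(breaks)) {
    if (length(breaks) < 1L || is.unsorted(breaks, strictly = TRUE))
      stop("breaks must be strictly increasing")
    cat <- matrix(findInterval(v, breaks, left.open = TRUE) + 1L, nrow(v))
    ncat <- length(breaks) + 1L
  } else {
    k <- asCount(k, "k")
    if (k < 2L) stop("quantile categorization needs k >= 2")
    n <- length(v)
    # equal-count classes from ranks; ties.method = "max" keeps ties together
    r <- rank(as.vector(v), ties.method = "max")
    cat <- matrix(as.integer(ceiling(r * k / n)), nrow(v))
    ncat <- k
  }
  new("SuitabilitySurface", values = v, categories = cat,
      nCategories = as.integer(ncat))
}

#' Pixel counts per suitability category
#'
#' @param surface A categorised \code{\link{SuitabilitySurface}}.
#' @return Named integer vector, one entry per ordinal category.
#' @export
categoryCounts <- function(surface) {
  stopifnot(is(surface, "SuitabilitySurface"))
  if (surface@nCategories == 0L)
    stop("surface has not been categorised; call categorizeSurface() first")
  stats::setNames(tabulate(surface@categories, nbins = surface@nCategories),
                  paste0("cat", seq_len(surface@nCategories)))
}
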
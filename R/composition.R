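#' @include AllClasses.R
NULL

#' Construct a landcover composition
#'
#' Builds a validated \code{\link{LandcoverComposition}} from named class
#' proportions. Classes not supplied default to 0; if \code{other} is not
#' supplied it is computed as the residual \code{1 - sum(named classes)},
#' mirroring its role as the catch-all class that never enters the habitat
#' model.
#'
#' @param ... Named proportions for any subset of
#'   \code{\link{landcoverClasses}} (e.g. \code{crp = 0.1,
#'   row_crop = 0.25}).
#' @param proportions Alternatively, a single named numeric vector.
#' @return A \code{LandcoverComposition}.
#' @examples
#' landcoverComposition(row_crop = 0.25, crp = 0.01)  # other = 0.74
#' @export
landcoverComposition <- function(..., proportions = NULL) {
  p <- if (is.null(proportions)) unlist(list(...)) else proportions
  if (length(p) == 0L)
    stop("at least one class proportion must be supplied")
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop("all proportions must be named")
  unknown <- setdiff(names(p), landcoverClasses)
  if (length(unknown) > 0L)
    stop(sprintf("unknown landcover class(es): %s (expected among: %s)",
                 paste(unknown, collapse = ", "),
                 paste(landcoverClasses, collapse = ", ")))
  if (anyDuplicated(names(p)))
    stop("duplicated class names in proportions")
  full <- stats::setNames(numeric(length(landcoverClasses)), landcoverClasses)
  full[names(p)] <- as.numeric(p)
  if (!"other" %in% names(p)) {
    named_sum <- sum(full[setdiff(landcoverClasses, "other")])
    if (named_sum > 1 + 1e-9)
      stop(sprintf("named class proportions sum to %.6f > 1", named_sum))
    full["other"] <- max(0, 1 - named_sum)
  }
  new("LandcoverComposition", proportions = full)
}

#' Coerce a named vector or composition to LandcoverComposition
#' @noRd
asComposition <- function(x) {
  if (is(x, "LandcoverComposition")) return(x)
  if (is.numeric(x) && !is.null(names(x)))
    return(landcoverComposition(proportions = x))
  stop("cannot interpret object as a landcover composition")
}

#' Apply a set of proportion deltas to a composition
#'
#' Shifts the named class proportions by the given amounts and recomputes
#' \code{other} as the residual, the batch analogue of moving the
#' management sliders away from a county's default composition.
#'
#' @param composition A \code{\link{LandcoverComposition}} (the baseline).
#' @param deltas Named numeric vector of changes for classes other than
#'   \code{other} (positive = more of that class).
#' @return A new validated \code{LandcoverComposition}.
#' @export
applyDeltas <- function(composition, deltas) {
  composition <- asComposition(composition)
  if (length(deltas) == 0L) return(composition)
  if (is.null(names(deltas)))
    stop("deltas must be named by landcover class")
  unknown <- setdiff(names(deltas), setdiff(landcoverClasses, "other"))
  if (length(unknown) > 0L)
    stop(sprintf("deltas allowed only for non-residual classes; got: %s",
                 paste(unknown, collapse = ", ")))
  p <- landcoverProportions(composition)
  p[names(deltas)] <- p[names(deltas)] + deltas
  named <- setdiff(landcoverClasses, "other")
  if (any(p[named] < -1e-12) || any(p[named] > 1 + 1e-12))
    stop("deltas push a class proportion outside [0, 1]")
  p[named] <- pmin(pmax(p[named], 0), 1)
  landcoverComposition(proportions = p[named])
}
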
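#' @include AllClasses.R composition.R utils.R
NULL

## CSV schema for county profile tables (proportions as fractions, not
## percent, so that write -> load round-trips without unit ambiguity).
profileColumns <- c("county_id", setdiff(landcoverClasses, "other"), "other",
                    "row_crop_yield", "row_crop_price",
                    "small_grain_yield", "small_grain_price",
                    "pasture_rental", "crp_rental")

#' Construct a county profile
#'
#' @param countyId Character identifier.
#' @param composition A \code{\link{LandcoverComposition}} or named
#'   proportion vector: the county's mean township composition.
#' @param rowCropYield,smallGrainYield Bushels/acre.
#' @param rowCropPrice,smallGrainPrice $/bushel.
#' @param pastureRental,crpRental $/acre/year.
#' @return A \code{\link{CountyProfile}}.
#' @export
countyProfile <- function(countyId, composition,
                          rowCropYield, rowCropPrice,
                          smallGrainYield, smallGrainPrice,
                          pastureRental, crpRental) {
  new("CountyProfile",
      countyId = as.character(countyId),
      meanComposition = asComposition(composition),
      cropYield = c(row_crop = as.numeric(rowCropYield),
                    small_grain = as.numeric(smallGrainYield)),
      cropPrice = c(row_crop = as.numeric(rowCropPrice),
                    small_grain = as.numeric(smallGrainPrice)),
      pastureRental = as.numeric(pastureRental),
      crpRental = as.numeric(crpRental))
}

#' Load county profiles from a CSV table
#'
#' Reads a county profile table (one row per county; see Details) and
#' returns a validated list of \code{\link{CountyProfile}} objects. If the
#' \code{other} column is absent the residual class is recomputed as
#' \code{1 - sum(named classes)} per row.
#'
#' @details Required columns: \code{county_id}; the six non-residual class
#'   proportions \code{crp, row_crop, small_grain, rangeland, trees,
#'   wetland} as fractions; \code{row_crop_yield}, \code{row_crop_price},
#'   \code{small_grain_yield}, \code{small_grain_price},
#'   \code{pasture_rental}, \code{crp_rental}. Optional: \code{other}.
#'
#' @param path Path to a CSV file with a header row.
#' @return Named list of \code{CountyProfile}, keyed by \code{county_id}.
#' @seealso \code{\link{writeProfiles}}, \code{\link{generateFixtureProfiles}}
#' @export
loadProfiles <- function(path) {
  if (!file.exists(path))
    stop(sprintf("profile file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  required <- setdiff(profileColumns, "other")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("profile table is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  named <- setdiff(landcoverClasses, "other")
  profiles <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    rid <- as.character(row[["county_id"]])
    p <- stats::setNames(as.numeric(row[named]), named)
    if (anyNA(p) || any(p < 0) || any(p > 1))
      stop(sprintf("row '%s': class proportion outside [0, 1]", rid))
    if (sum(p) > 1 + 1e-9)
      stop(sprintf("row '%s': named class proportions sum to %.6f > 1",
                   rid, sum(p)))
    if ("other" %in% names(df) && !is.na(row[["other"]])) {
      p <- c(p, other = as.numeric(row[["other"]]))
    }
    econ <- c(row[["row_crop_yield"]], row[["row_crop_price"]],
              row[["small_grain_yield"]], row[["small_grain_price"]],
              row[["pasture_rental"]], row[["crp_rental"]])
    if (anyNA(econ) || any(econ < 0))
      stop(sprintf("row '%s': negative or missing economic value", rid))
    profiles[[i]] <- countyProfile(
      rid, landcoverComposition(proportions = p),
      rowCropYield = row[["row_crop_yield"]],
      rowCropPrice = row[["row_crop_price"]],
      smallGrainYield = row[["small_grain_yield"]],
      smallGrainPrice = row[["small_grain_price"]],
      pastureRental = row[["pasture_rental"]],
      crpRental = row[["crp_rental"]])
  }
  names(profiles) <- vapply(profiles, function(p) p@countyId, character(1))
  profiles
}

#' Write county profiles to a CSV table
#'
#' Inverse of \code{\link{loadProfiles}}: writes one row per profile using
#' the documented column schema (proportions as fractions).
#'
#' @param profiles List of \code{\link{CountyProfile}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  rows <- lapply(profiles, function(pr) {
    p <- landcoverProportions(pr)
    data.frame(county_id = pr@countyId,
               crp = p[["crp"]], row_crop = p[["row_crop"]],
               small_grain = p[["small_grain"]],
               rangeland = p[["rangeland"]], trees = p[["trees"]],
               wetland = p[["wetland"]], other = p[["other"]],
               row_crop_yield = pr@cropYield[["row_crop"]],
               row_crop_price = pr@cropPrice[["row_crop"]],
               small_grain_yield = pr@cropYield[["small_grain"]],
               small_grain_price = pr@cropPrice[["small_grain"]],
               pasture_rental = pr@pastureRental,
               crp_rental = pr@crpRental)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate synthetic county profiles
#'
#' Produces a seeded, reproducible set of synthetic county profiles with
#' the schema of a NASS-style county table: mean compositions drawn from a
#' symmetric Dirichlet distribution over the 7-class simplex (gamma draws
#' renormalised; concentration 2 avoids degenerate near-vertex draws) and
#' economics drawn uniformly from order-of-magnitude-realistic ranges
#' (yields 20-200 bu/acre, prices $2-15/bushel, rentals $10-250/acre/yr).
#' Values are placeholders standing in for real county data, not estimates
#' of any actual county.
#'
#' @param nCounties Number of counties (>= 1).
#' @param seed Integer seed; identical seeds give identical profiles.
#' @param path Optional CSV path; if supplied the profiles are also
#'   written via \code{\link{writeProfiles}}.
#' @return Named list of \code{\link{CountyProfile}}.
#' @export
generateFixtureProfiles <- function(nCounties, seed, path = NULL) {
  nCounties <- asCount(nCounties, "nCounties")
  withSeed(seed, {
    profiles <- lapply(seq_len(nCounties), function(i) {
      g <- stats::rgamma(length(landcoverClasses), shape = 2, rate = 1)
      p <- stats::setNames(g / sum(g), landcoverClasses)
      countyProfile(
        sprintf("SYN%03d", i),
        landcoverComposition(proportions = p),
        rowCropYield = stats::runif(1, 20, 200),
        rowCropPrice = stats::runif(1, 2, 15),
        smallGrainYield = stats::runif(1, 20, 200),
        smallGrainPrice = stats::runif(1, 2, 15),
        pastureRental = stats::runif(1, 10, 250),
        crpRental = stats::runif(1, 10, 250))
    })
    names(profiles) <- vapply(profiles, function(p) p@countyId, character(1))
    if (!is.null(path)) writeProfiles(profiles, path)
    profiles
  })
}
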
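#' @include AllClasses.R
NULL

## Rasters are exported as ESRI ASCII grids: a plain-text, GIS-readable
## format. The township deliberately represents no real place, so a local
## coordinate origin (0, 0) is used and no CRS is attached.

#' Write a matrix as an ESRI ASCII grid
#'
#' @param m Numeric or integer matrix (row 1 = northernmost row).
#' @param path Output path (conventionally .asc).
#' @param cellSize Cell edge length in map units (meters).
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(m, path, cellSize = 100) {
  stopifnot(is.matrix(m))
  header <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.10g", cellSize),
    "NODATA_value -9999")
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid written by \code{\link{writeAsciiGrid}}
#'
#' @param path Path to the .asc file.
#' @return Numeric matrix with attribute \code{cellSize}.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  vals <- stats::setNames(vapply(hdr, `[`, character(1), 2L),
                          tolower(vapply(hdr, `[`, character(1), 1L)))
  nc <- as.integer(vals[["ncols"]])
  nr <- as.integer(vals[["nrows"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  attr(m, "cellSize") <- as.numeric(vals[["cellsize"]])
  m
}

#' Write a township grid's class-code raster and code table
#'
#' Writes the label raster (full buffered extent) as an ASCII grid plus a
#' companion CSV mapping integer codes to landcover class names.
#'
#' @param grid A \code{\link{TownshipGrid}}.
#' @param path Output .asc path; the code table goes to
#'   \code{<path>.codes.csv}.
#' @return \code{path}, invisibly.
#' @export
writeTownshipRaster <- function(grid, path) {
  stopifnot(is(grid, "TownshipGrid"))
  writeAsciiGrid(grid@labels, path, cellSize = grid@pixelSize)
  utils::write.csv(
    data.frame(code = seq_along(landcoverClasses),
               class = landcoverClasses),
    paste0(path, ".codes.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the layers of a focal proportion stack
#'
#' One ASCII grid per covariate, named \code{<prefix>_<covariate>.asc}.
#'
#' @param stack A \code{\link{FocalProportionStack}}.
#' @param prefix Output path prefix.
#' @param cellSize Cell size in meters.
#' @return Character vector of written paths, invisibly.
#' @export
writeStackRasters <- function(stack, prefix, cellSize = 100) {
  stopifnot(is(stack, "FocalProportionStack"))
  paths <- vapply(modelCovariates, function(cl) {
    p <- sprintf("%s_%s.asc", prefix, cl)
    writeAsciiGrid(stack@layers[[cl]], p, cellSize = cellSize)
    p
  }, character(1))
  invisible(paths)
}
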
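# Shared helpers: brute-force oracles and small fixture builders.

# Exhaustive double-loop recount of a circular-window class proportion:
# the independent oracle for focalProportion(). Works directly on the
# buffered label matrix.
bruteForceFocal <- function(grid, class, radius) {
  lab <- gridLabels(grid)
  code <- match(class, landcoverClasses)
  b <- grid@bufferPx
  out <- matrix(NA_real_, grid@coreRows, grid@coreCols)
  offsets <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offsets <- offsets[offsets$dy^2 + offsets$dx^2 <= radius^2, ]
  ncell <- nrow(offsets)
  for (i in seq_len(grid@coreRows)) {
    for (j in seq_len(grid@coreCols)) {
      hits <- 0L
      for (k in seq_len(ncell)) {
        if (lab[b + i + offsets$dy[k], b + j + offsets$dx[k]] == code)
          hits <- hits + 1L
      }
      out[i, j] <- hits / ncell
    }
  }
  out
}

# A focal stack with every layer constant at `value` on an nr x nc extent.
constantStack <- function(value = 0, nr = 3, nc = 3,
                          radii = defaultScaleMap()) {
  layers <- stats::setNames(
    rep(list(matrix(value, nr, nc)), length(modelCovariates)),
    modelCovariates)
  new("FocalProportionStack", layers = layers, radii = radii)
}

# A synthetic county profile with round economics for hand arithmetic.
testProfile <- function(composition = landcoverComposition(
                          crp = 0.1, row_crop = 0.3, small_grain = 0.1,
                          rangeland = 0.2, trees = 0.05, wetland = 0.05),
                        rowCropYield = 150, rowCropPrice = 4,
                        smallGrainYield = 50, smallGrainPrice = 5,
                        pastureRental = 30, crpRental = 100) {
  countyProfile("TEST", composition,
                rowCropYield = rowCropYield, rowCropPrice = rowCropPrice,
                smallGrainYield = smallGrainYield,
                smallGrainPrice = smallGrainPrice,
                pastureRental = pastureRental, crpRental = crpRental)
}

# Named acre vectors over all classes, zeros except those supplied.
acresVector <- function(...) {
  a <- stats::setNames(numeric(length(landcoverClasses)), landcoverClasses)
  supplied <- unlist(list(...))
  a[names(supplied)] <- supplied
  a
}
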
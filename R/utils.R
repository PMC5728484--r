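## Internal helpers shared across modules.

#' Run code under a temporary RNG seed, restoring global RNG state
#' @noRd
withSeed <- function(seed, code) {
  seed <- asCount(seed, "seed", allow_zero = TRUE, allow_negative = TRUE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

#' Validate an integer-valued scalar
#' @noRd
asCount <- function(x, what, allow_zero = FALSE, allow_negative = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x))
    stop(sprintf("%s must be a single integer value", what))
  if (!allow_negative && x < 0)
    stop(sprintf("%s must be non-negative", what))
  if (!allow_zero && !allow_negative && x == 0)
    stop(sprintf("%s must be >= 1", what))
  as.integer(x)
}
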
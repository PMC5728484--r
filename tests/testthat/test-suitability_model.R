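test_that("the linear predictor reproduces hand-computed values", {
  zero <- setNames(numeric(6), modelCovariates)

  # all covariates zero -> the intercept alone
  expect_identical(linearPredictor(zero, defaultCoefficients()), 3.07)

  # null model: everything zero
  null <- coefficientSet(intercept = 0,
                         slopes = setNames(numeric(10), slopes <- c(
                           "rangeland", "crp", "row_crop", "row_crop2",
                           "row_crop3", "small_grain", "small_grain2",
                           "small_grain3", "trees", "wetland")))
  expect_identical(linearPredictor(zero, null), 0)

  # cubic row-crop polynomial from one shared focal value:
  # 0.5 + 0.25 + 0.125 = 0.875
  cs <- coefficientSet(intercept = 0, slopes = setNames(
    c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0), slopes))
  v <- zero; v[["row_crop"]] <- 0.5
  expect_equal(linearPredictor(v, cs), 0.875)

  expect_error(linearPredictor(zero[-1], defaultCoefficients()),
               "missing covariate")
  expect_error(linearPredictor(replace(zero, 1, 1.5),
                               defaultCoefficients()), "\\[0, 1\\]")
})

test_that("surface prediction is the exponentiated predictor everywhere", {
  # all-zero stack -> constant exp(3.07) ~ 21.54
  s <- predictSurface(constantStack(0), defaultCoefficients())
  expect_equal(unique(as.vector(suitabilityValues(s))), exp(3.07))
  expect_equal(exp(3.07), 21.54, tolerance = 2e-4)
  expect_true(all(suitabilityValues(s) > 0))

  # homogeneous 100% rangeland landscape -> closed form exp(3.07 + a)
  a <- 1.5
  grid <- generateTownship(landcoverComposition(rangeland = 1),
                           coreRows = 6, coreCols = 6, bufferPx = 50)
  surf <- predictSurface(computeStack(grid), defaultCoefficients())
  expect_equal(unique(as.vector(suitabilityValues(surf))), exp(3.07 + a))

  # log-link identity on a heterogeneous landscape
  comp <- landcoverComposition(row_crop = 0.3, crp = 0.1, trees = 0.1)
  g2 <- generateTownship(comp, coreRows = 12, coreCols = 12,
                         bufferPx = 50, seed = 9)
  st <- computeStack(g2)
  surf2 <- predictSurface(st, defaultCoefficients())
  eta <- vapply(seq_len(144), function(i) {
    v <- vapply(st@layers, `[`, numeric(1), i)
    linearPredictor(v, defaultCoefficients())
  }, numeric(1))
  expect_equal(as.vector(log(suitabilityValues(surf2))), eta,
               tolerance = 1e-12)

  # overflow is reported with the offending pixel
  big <- coefficientSet(intercept = 1000, slopes = setNames(
    c(rep(0, 9), 0), c("rangeland", "crp", "row_crop", "row_crop2",
                       "row_crop3", "small_grain", "small_grain2",
                       "small_grain3", "trees", "wetland")))
  expect_error(predictSurface(constantStack(0), big), "non-finite")
})

test_that("raising a positive-slope covariate never lowers suitability", {
  cs <- defaultCoefficients()  # crp slope is positive
  base <- setNames(runif(6, 0, 0.5), modelCovariates)
  vals <- vapply(seq(0, 1, by = 0.05), function(cv) {
    v <- base; v[["crp"]] <- cv
    linearPredictor(v, cs)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("categorization is ordinal, monotone, and balanced", {
  # constant surface collapses to one category
  s <- categorizeSurface(predictSurface(constantStack(0),
                                        defaultCoefficients()), k = 5)
  expect_length(unique(as.vector(suitabilityCategories(s))), 1L)

  # explicit thresholds
  surf <- new("SuitabilitySurface",
              values = matrix(c(5, 20, 50), 1),
              categories = matrix(integer(0), 0, 0), nCategories = 0L)
  cut <- categorizeSurface(surf, breaks = c(10, 30))
  expect_identical(as.vector(suitabilityCategories(cut)), c(1L, 2L, 3L))
  expect_error(categorizeSurface(surf, breaks = c(30, 10)),
               "strictly increasing")

  # quantile categories of 9324 distinct values: counts within 1 of n/k
  set.seed(3)
  v <- matrix(sample(seq_len(9324)) + 0.5, nrow = 84)
  surf2 <- new("SuitabilitySurface", values = v,
               categories = matrix(integer(0), 0, 0), nCategories = 0L)
  cut2 <- categorizeSurface(surf2, k = 5)
  cc <- categoryCounts(cut2)
  expect_identical(sum(cc), 9324L)
  expect_true(all(abs(cc - 9324 / 5) <= 1))

  # monotone: category order respects value order
  o <- order(v)
  expect_false(is.unsorted(suitabilityCategories(cut2)[o]))
})
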
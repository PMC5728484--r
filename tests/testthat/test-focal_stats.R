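test_that("kernel cell counts match lattice enumeration", {
  expect_identical(buildKernel(0)@cellCount, 1L)
  expect_identical(buildKernel(1)@cellCount, 5L)
  expect_identical(buildKernel(10)@cellCount, 317L)
  expect_error(buildKernel(-1), "non-negative")

  # independent enumeration over a range of radii
  for (r in c(2, 3, 5, 7, 50)) {
    enum <- sum(outer(seq(-r, r)^2, seq(-r, r)^2, `+`) <= r^2)
    expect_identical(buildKernel(r)@cellCount, as.integer(enum))
  }
})

test_that("focal proportions equal a brute-force recount on random grids", {
  set.seed(21)
  kernel <- buildKernel(3)
  for (rep in 1:20) {
    g <- rgamma(7, 1)
    comp <- landcoverComposition(proportions = setNames(g / sum(g),
                                                        landcoverClasses))
    grid <- generateTownship(comp, coreRows = 30, coreCols = 30,
                             bufferPx = 3, seed = rep)
    cl <- sample(landcoverClasses, 1)
    fast <- focalProportion(grid, cl, kernel)
    # integer-count arithmetic both sides: agreement must be bit-exact
    expect_identical(fast, bruteForceFocal(grid, cl, 3))
  }
})

test_that("homogeneous landscapes and point features give exact fractions", {
  grid <- generateTownship(landcoverComposition(crp = 1),
                           coreRows = 12, coreCols = 12, bufferPx = 10)
  k10 <- buildKernel(10)
  expect_true(all(focalProportion(grid, "crp", k10) == 1))
  expect_true(all(focalProportion(grid, "trees", k10) == 0))

  # one wetland pixel at a core pixel's centre -> 1/317 there
  grid2 <- generateTownship(landcoverComposition(other = 1),
                            coreRows = 21, coreCols = 21, bufferPx = 10)
  lab <- gridLabels(grid2)
  lab[10 + 11, 10 + 11] <- match("wetland", landcoverClasses)
  grid2@labels <- lab  # hand-placed feature; bypasses count invariant
  w <- habscape::focalProportion(grid2, "wetland", k10)
  expect_equal(w[11, 11], 1 / 317)
})

test_that("window must fit inside the buffer", {
  grid <- generateTownship(landcoverComposition(crp = 1),
                           coreRows = 5, coreCols = 5, bufferPx = 2)
  expect_error(focalProportion(grid, "crp", buildKernel(3)),
               "radius \\(3 px\\).*buffer \\(2 px\\)")
})

test_that("focal proportions over all seven classes sum to one", {
  set.seed(8)
  g <- rgamma(7, 1)
  comp <- landcoverComposition(proportions = setNames(g / sum(g),
                                                      landcoverClasses))
  grid <- generateTownship(comp, coreRows = 15, coreCols = 15,
                           bufferPx = 5, seed = 2)
  kernel <- buildKernel(5)
  # fractions share the kernel denominator, so integer window counts
  # must sum to the kernel cell count at every pixel
  counts <- Reduce(`+`, lapply(landcoverClasses, function(cl)
    round(focalProportion(grid, cl, kernel) * kernel@cellCount)))
  expect_true(all(counts == kernel@cellCount))
  total <- Reduce(`+`, lapply(landcoverClasses, function(cl)
    focalProportion(grid, cl, kernel)))
  expect_equal(max(abs(total - 1)), 0, tolerance = 1e-12)
})

test_that("focal values are translation invariant", {
  comp <- landcoverComposition(trees = 0.3, crp = 0.2)
  grid <- generateTownship(comp, coreRows = 20, coreCols = 20,
                           bufferPx = 6, seed = 13)
  # shift the whole label grid by (1, 1); interior core values must shift too
  shifted <- grid
  lab <- gridLabels(grid)
  labS <- lab
  labS[2:nrow(lab), 2:ncol(lab)] <- lab[1:(nrow(lab) - 1),
                                        1:(ncol(lab) - 1)]
  shifted@labels <- labS
  f0 <- focalProportion(grid, "trees", buildKernel(4))
  f1 <- focalProportion(shifted, "trees", buildKernel(4))
  expect_identical(f1[2:20, 2:20], f0[1:19, 1:19])
})

test_that("the covariate stack composes focalProportion at mapped radii", {
  comp <- landcoverComposition(crp = 1)
  grid <- generateTownship(comp, coreRows = 8, coreCols = 8, bufferPx = 50)
  stack <- computeStack(grid)
  expect_true(all(stack@layers$crp == 1))
  for (cl in setdiff(modelCovariates, "crp"))
    expect_true(all(stack@layers[[cl]] == 0))

  # layer identity with a direct focalProportion call
  comp2 <- landcoverComposition(trees = 0.4, rangeland = 0.3)
  grid2 <- generateTownship(comp2, coreRows = 10, coreCols = 10,
                            bufferPx = 50, seed = 4)
  stack2 <- computeStack(grid2)
  sm <- defaultScaleMap()
  expect_identical(stack2@layers$trees,
                   focalProportion(grid2, "trees",
                                   buildKernel(sm[["trees"]])))
  expect_identical(stack2@layers$rangeland,
                   focalProportion(grid2, "rangeland",
                                   buildKernel(sm[["rangeland"]])))

  # configuration errors
  expect_error(computeStack(grid2, c(crp = 10)), "missing covariate")
  badMap <- defaultScaleMap(); badMap[["crp"]] <- 7L
  expect_error(computeStack(grid2, badMap), "among \\{10, 50\\}")
})

test_that("stack layer means reflect the landscape composition", {
  # 25% row crop / 1% CRP worked example: the mean focal row-crop
  # proportion over the core tracks the generating fraction
  comp <- landcoverComposition(row_crop = 0.25, crp = 0.01)
  grid <- generateTownship(comp, seed = 17)
  stack <- computeStack(grid)
  expect_equal(mean(stack@layers$row_crop), 0.25, tolerance = 0.02)
  expect_equal(mean(stack@layers$crp), 0.01, tolerance = 0.02)
})
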
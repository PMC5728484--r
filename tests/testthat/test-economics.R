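test_that("acre conversion is linear and uses 2.47105381 acres/ha", {
  full <- compositionToAcres(landcoverComposition(other = 1), 9324)
  expect_equal(full[["other"]], 9324 * 2.47105381)
  expect_equal(sum(full), 9324 * 2.47105381)

  half <- landcoverComposition(row_crop = 0.5)
  quarter <- landcoverComposition(row_crop = 0.25)
  expect_equal(compositionToAcres(half, 9324)[["row_crop"]],
               2 * compositionToAcres(quarter, 9324)[["row_crop"]])
  expect_equal(compositionToAcres(quarter, 9324)[["crp"]], 0)
})

test_that("gross income counts crops and pasture, never CRP or habitat", {
  pr <- testProfile()
  expect_equal(grossIncome(acresVector(), pr), 0)
  expect_equal(grossIncome(acresVector(row_crop = 100), pr),
               100 * 150 * 4)  # 60,000 $/yr
  expect_equal(grossIncome(acresVector(rangeland = 100), pr), 100 * 30)
  # CRP, trees, wetland, other are income-neutral
  expect_equal(grossIncome(acresVector(crp = 500, trees = 50,
                                       wetland = 50, other = 100), pr), 0)
})

test_that("agricultural cost prices income loss plus new CRP contracts", {
  pr <- testProfile()
  base <- acresVector(row_crop = 100)
  scen <- acresVector(crp = 100)

  # 100 acres row crop -> CRP: 10 yr x $60,000 income loss + 10 yr x
  # $100/ac x 100 ac of new contracts = 700,000
  expect_equal(agriculturalCost(base, scen, pr, horizon = 10), 700000)

  # identity scenario costs nothing
  expect_equal(agriculturalCost(base, base, pr, horizon = 10), 0)

  # horizon linearity
  expect_equal(agriculturalCost(base, scen, pr, horizon = 20),
               2 * agriculturalCost(base, scen, pr, horizon = 10))

  # doubling the income difference doubles the non-CRP term
  base2 <- acresVector(row_crop = 200)
  expect_equal(agriculturalCost(base2, acresVector(), pr, horizon = 10),
               2 * agriculturalCost(base, acresVector(), pr, horizon = 10))

  # retiring CRP charges no rental under increment mode; "all" mode
  # charges every scenario CRP acre
  rev <- agriculturalCost(acresVector(crp = 100), acresVector(crp = 50),
                          pr, horizon = 10)
  expect_equal(rev, 0)
  expect_equal(agriculturalCost(acresVector(crp = 100),
                                acresVector(crp = 50), pr, horizon = 10,
                                crpMode = "all"), 50 * 100 * 10)

  # a scenario more profitable than baseline yields a negative cost
  expect_lt(agriculturalCost(acresVector(), acresVector(row_crop = 10),
                             pr, horizon = 10), 0)
})

test_that("management costs are one-sided at the published unit rates", {
  costs <- unitManagementCosts()  # $650 and $6250 per acre
  base <- acresVector(trees = 10, wetland = 10)

  rm1 <- managementCost(base, acresVector(trees = 9, wetland = 10), costs)
  expect_equal(rm1[["tree_cost"]], 650)
  expect_equal(rm1[["wetland_cost"]], 0)

  add1 <- managementCost(base, acresVector(trees = 10, wetland = 11), costs)
  expect_equal(add1[["tree_cost"]], 0)
  expect_equal(add1[["wetland_cost"]], 6250)

  # planting trees and draining wetlands are both free to the manager
  opp <- managementCost(base, acresVector(trees = 20, wetland = 0), costs)
  expect_equal(unname(opp), c(0, 0))

  # monotone one-sidedness across a sweep of scenario acreages
  treeCosts <- vapply(0:20, function(t)
    managementCost(base, acresVector(trees = t, wetland = 10),
                   costs)[["tree_cost"]], numeric(1))
  expect_true(all(diff(treeCosts) <= 0) && all(treeCosts >= 0))
  wetCosts <- vapply(0:20, function(w)
    managementCost(base, acresVector(trees = 10, wetland = w),
                   costs)[["wetland_cost"]], numeric(1))
  expect_true(all(diff(wetCosts) >= 0) && all(wetCosts >= 0))
})

test_that("total cost composes the component operations", {
  pr <- testProfile()
  area <- 9324
  toProp <- function(acres) acres / (area * 2.47105381)

  base <- landcoverComposition(proportions = c(
    crp = 0, row_crop = toProp(100), small_grain = 0, rangeland = 0,
    trees = toProp(10), wetland = toProp(3),
    other = 1 - toProp(113)))
  scen <- landcoverComposition(proportions = c(
    crp = toProp(100), row_crop = 0, small_grain = 0, rangeland = 0,
    trees = 0, wetland = toProp(5), other = 1 - toProp(105)))

  cb <- totalCost(base, scen, pr, townshipArea = area, horizon = 10)
  # 700,000 (agricultural) + 10 ac x $650 + 2 ac x $6250
  expect_equal(cb@agriculturalCost, 700000, tolerance = 1e-9)
  expect_equal(cb@treeCost, 6500, tolerance = 1e-9)
  expect_equal(cb@wetlandCost, 12500, tolerance = 1e-9)
  expect_equal(cb@total, 719000, tolerance = 1e-9)
  expect_equal(cb@total, cb@agriculturalCost + cb@treeCost + cb@wetlandCost)

  # identity scenario: all four fields zero
  cb0 <- totalCost(base, base, pr, townshipArea = area)
  expect_equal(cb0@total, 0)
  expect_equal(cb0@agriculturalCost, 0)
  expect_equal(cb0@treeCost, 0)
  expect_equal(cb0@wetlandCost, 0)

  # unit invariance: acre-space arithmetic agrees with the
  # proportion -> acre pipeline to high relative accuracy
  direct <- agriculturalCost(acresVector(row_crop = 100, trees = 10,
                                         wetland = 3),
                             acresVector(crp = 100, wetland = 5),
                             pr, horizon = 10)
  expect_equal(cb@agriculturalCost, direct,
               tolerance = 1e-6 * abs(direct))
})

test_that("cost serialisation mirrors the breakdown", {
  pr <- testProfile()
  cb <- totalCost(landcoverComposition(row_crop = 0.1),
                  landcoverComposition(crp = 0.1), pr)
  lst <- costAsList(cb)
  expect_identical(lst$total, cb@total)
  expect_identical(lst$county_id, "TEST")
  txt <- costSummaryText(cb)
  expect_true(any(grepl("Total cost", txt)))
})
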
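test_that("ratio and atom fraction are mutually inverse", {
  expect_equal(atomFraction(0), 0)
  expect_equal(atomFraction(1), 0.5)
  expect_equal(atomFraction(0.0117), 0.0117 / 1.0117, tolerance = 1e-12)
  grid <- c(0, 1e-6, 0.0043, 0.0117, 0.05, 0.119, 1, 10)
  expect_equal(isotopeRatio(atomFraction(grid)), grid, tolerance = 1e-12)
  expect_error(isotopeRatio(1), "atom fraction")
  expect_error(atomFraction(-0.1), "ratio")
})

test_that("relative activity is the excess over natural abundance, scaled by labelling", {
  cond <- LabelingConditions(sourceFraction = c(C = 0.119, N = 0.018),
                             naturalAbundance = c(C = 0.0111, N = 0.0037))
  expect_equal(as.numeric(relativeActivity(0.0037, cond, "N")), 0)
  expect_equal(as.numeric(relativeActivity(0.018, cond, "N")), 1)
  expect_equal(as.numeric(relativeActivity(0.00484, cond, "N")),
               0.00114 / 0.0143, tolerance = 1e-10)
  clipped <- relativeActivity(0.001, cond, "N")
  expect_equal(as.numeric(clipped), 0)
  expect_true(attr(clipped, "clipped"))
  expect_error(LabelingConditions(sourceFraction = c(C = 0.119, N = 0.001),
                                  naturalAbundance = c(C = 0.0111, N = 0.0037)),
               "natural abundance")
})

test_that("relative activity is increasing in enrichment, decreasing in labelling", {
  aGrid <- seq(0.004, 0.017, length.out = 20)
  cond <- LabelingConditions()
  acts <- as.numeric(relativeActivity(aGrid, cond, "N"))
  expect_true(all(diff(acts) > 0))
  xiGrid <- seq(0.01, 0.05, length.out = 10)
  actXi <- vapply(xiGrid, function(xi) {
    cc <- LabelingConditions(sourceFraction = c(C = 0.119, N = xi))
    as.numeric(relativeActivity(0.008, cc, "N"))
  }, 0)
  expect_true(all(diff(actXi) < 0))
})

test_that("growth rate is Eq-style: activity x 2 / t", {
  expect_equal(growthRate(0, 5), 0)
  expect_equal(growthRate(0.5, 1), 1)
  expect_equal(growthRate(0.08, 1), 0.16)
  expect_equal(growthRate(1, 1), 2)
  # linear in activity, scales with 1/t
  act <- seq(0, 1, 0.1)
  expect_equal(growthRate(act, 2), act * 2 / 2)
  expect_error(growthRate(0.1, 0), "t must be")
})

test_that("prolate-spheroid biovolume", {
  expect_equal(biovolumeProlateSpheroid(1, 1), pi / 6)
  expect_equal(biovolumeProlateSpheroid(2, 1), pi / 3)
  expect_equal(biovolumeProlateSpheroid(1.6, 1.0), 0.8378, tolerance = 1e-4)
  expect_error(biovolumeProlateSpheroid(0.5, 1), "axes swapped")
})

test_that("cell contents convert biovolume and C:N to fg C and fg N", {
  cc <- cellContents(1, cnMolar = 6.625, conversion = 250)
  expect_equal(cc$carbonFg, 250)
  cc2 <- cellContents(2, cnMolar = 5, conversion = list(a = 120, b = 0))
  expect_equal(cc2$carbonFg, 120)  # b = 0 degenerates to constant per cell
  expect_equal(cc2$nitrogenFg, 120 / 5 * (14.007 / 12.011), tolerance = 1e-10)
  expect_equal(cellContents(1, 5, list(a = 120, b = 0))$nitrogenFg, 27.99,
               tolerance = 1e-3)
  expect_error(cellContents(1, cnMolar = 0), "C:N")
})

test_that("cellular assimilation chains activity, content and time", {
  expect_equal(cellularAssimilation(0, 100, 1), 0)
  expect_equal(cellularAssimilation(0.1, 100, 1), 10)
  contentC <- cellContents(0.84, cnMolar = 5, conversion = 250)$carbonFg
  expect_equal(contentC, 210)
  expect_equal(cellularAssimilation(0.08, contentC, 1), 16.8)
})

test_that("older-biomass substrate scenario raises the inferred activity", {
  cond <- LabelingConditions(sourceFraction = c(C = 0.119, N = 0.018),
                             naturalAbundance = c(C = 0.0111, N = 0.0037))
  # endpoint at the source labelling reduces to relativeActivity
  expect_equal(as.numeric(alternativeSubstrateActivity(0.0065, 0.018, cond, "N")),
               as.numeric(relativeActivity(0.0065, cond, "N")))
  # epibiont at the endpoint composition: full turnover
  expect_equal(as.numeric(alternativeSubstrateActivity(0.0077, 0.0077, cond, "N")), 1)
  expect_equal(as.numeric(alternativeSubstrateActivity(0.00484, 0.0077, cond, "N")),
               0.00114 / 0.0040, tolerance = 1e-10)
  expect_error(alternativeSubstrateActivity(0.005, 0.002, cond, "N"),
               "natural abundance")
})

test_that("substrate-swap ratio identity holds to numerical precision", {
  cond <- LabelingConditions()
  na <- naturalAbundance(cond, "N"); xi <- sourceFraction(cond, "N")
  for (aEnd in c(0.006, 0.009, 0.015)) {
    for (aEpi in c(0.004, 0.0055, 0.0058)) {
      r <- as.numeric(alternativeSubstrateActivity(aEpi, aEnd, cond, "N")) /
        as.numeric(relativeActivity(aEpi, cond, "N"))
      expect_equal(r, (xi - na) / (aEnd - na), tolerance = 1e-12)
    }
  }
})

test_that("cellRates composes the per-cell chain with detection flags", {
  cond <- LabelingConditions()
  m <- data.frame(
    label = 1:2, cellType = "epibiont", nPixels = 50,
    ratioC = c(0.05, 0.01), validC = TRUE,
    ratioN = c(0.006, 0.004), validN = TRUE,
    lengthUm = c(1.6, 1.6), widthUm = c(1.0, 1.0),
    retainedC = c(TRUE, FALSE), retainedN = c(TRUE, TRUE))
  r <- cellRates(m, cond, cnMolar = 5, conversion = 250)
  expect_equal(r$volume, rep(biovolumeProlateSpheroid(1.6, 1), 2))
  aC <- atomFraction(0.05)
  expect_equal(r$activityC[1],
               as.numeric(relativeActivity(aC, cond, "C")))
  expect_true(is.na(r$activityC[2]))  # not retained
  expect_equal(r$growthN, r$activityN * 2)
  expect_equal(r$assimC[1], r$activityC[1] * r$carbonFg[1])
})
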
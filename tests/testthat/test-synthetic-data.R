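test_that("a cell with zero 15N abundance gives no 12C15N counts beyond background", {
  scene <- makeCellScene(atomC = 0.05, atomN = 0)
  sim <- simulateIonStack(scene, quickAcq(planes = 3), seed = 1)
  expect_true(all(ionCounts(sim$stack, "12C15N") == 0))
  expect_gt(sum(ionCounts(sim$stack, "12C14N")), 0)
})

test_that("the same seed reproduces a stack bit-identically", {
  scene <- makeCellScene()
  acq <- quickAcq(planes = 3, drift = cbind(c(0, 1, -1), c(0, 0, 2)))
  a <- simulateIonStack(scene, acq, seed = 42)
  b <- simulateIonStack(scene, acq, seed = 42)
  expect_identical(a$stack@counts, b$stack@counts)
  expect_identical(a$mask, b$mask)
})

test_that("total CN counts over a cell match the Poisson sum expectation", {
  # CN yield 20 per px per plane, 40 planes; expectation = 20 * npx * 40,
  # observed within 4 sqrt(expectation)
  scene <- makeCellScene(atomN = 0.1, yieldCN = 20)
  sim <- simulateIonStack(scene, quickAcq(planes = 40), seed = 7)
  npx <- sum(sim$mask == 1)
  sumCell <- function(arr) sum(apply(arr, 3, function(m) sum(m[sim$mask == 1])))
  tot <- sumCell(ionCounts(sim$stack, "12C14N")) +
    sumCell(ionCounts(sim$stack, "12C15N"))
  expected <- 20 * npx * 40
  expect_lt(abs(tot - expected), 4 * sqrt(expected))
})

test_that("per-species cell totals concentrate around expectation across seeds", {
  scene <- makeCellScene(atomC = 0.05, atomN = 0.02, yieldC = 30, yieldCN = 40)
  acq <- quickAcq(size = 32, planes = 4)
  ok <- 0L
  nSeeds <- 50L
  for (s in seq_len(nSeeds)) {
    sim <- simulateIonStack(scene, acq, seed = s)
    inCell <- sim$mask == 1
    npx <- sum(inCell)
    hit <- TRUE
    for (sp in c("12C", "13C", "12C14N", "12C15N")) {
      lam <- sim$expected[[sp]][inCell][1] * npx * 4
      obs <- sum(apply(ionCounts(sim$stack, sp), 3, function(m) sum(m[inCell])))
      if (abs(obs - lam) > 5 * sqrt(lam)) hit <- FALSE
    }
    ok <- ok + hit
  }
  expect_gte(ok / nSeeds, 0.99 - 1e-9)
})

test_that("drift that pushes a cell fully out of frame is an error", {
  scene <- makeCellScene(radius = 4, size = 32)
  drift <- rbind(c(0, 0), c(0, 30))
  expect_error(simulateIonStack(scene, quickAcq(size = 32, planes = 2,
                                                drift = drift)),
               "fully out of frame")
})

test_that("invalid atom fractions and geometry are rejected at construction", {
  expect_error(makeCellScene(atomC = 1.2), "atom fraction")
  cells <- sceneCells(makeCellScene())
  cells$lengthUm <- 0.1  # shorter than width
  expect_error(ColonyScene(cells, background = c(C = 0, CN = 0, P = 0, S = 0),
                           pixelSize = 0.1), "length")
})

test_that("radiotracer series with zero uptake equals the controls", {
  d <- RadiotracerDesign(rate = 0)
  sim <- simulateRadiotracer(d, noise = FALSE)
  s <- sim$samples
  ctrl <- s[s$type == "control" & s$bottle == "control_filtered", "counts"]
  for (r in paste0("R", 1:5))
    expect_equal(s[s$bottle == r, "counts"], ctrl)
})

test_that("radiotracer incorporation plateaus at pool exhaustion", {
  d <- RadiotracerDesign(rate = 2.25, dip = 34,
                         times = c(0, 6, 12, 15.2, 18, 24),
                         bindingFraction = 0, countingDelayDays = 0)
  sim <- simulateRadiotracer(d, noise = FALSE)
  expect_equal(sim$truth$exhaustionH, 34 / 2.25)
  f <- sim$samples[sim$samples$bottle == "R1", "counts"] / d@totalCounts
  expect_lt(f[3], 1)               # 12 h: still linear
  expect_equal(f[4], 1)            # past 15.11 h: pool exhausted
  expect_equal(f[6], 1)
  # linear regime slope = rate / dip
  expect_equal((f[2] - f[1]) / 6, 2.25 / 34, tolerance = 1e-12)
})

test_that("a counting delay of one half-life halves every recorded count", {
  d0 <- RadiotracerDesign(countingDelayDays = 0)
  d1 <- RadiotracerDesign(countingDelayDays = 25.4)
  a <- simulateRadiotracer(d0, noise = FALSE)
  b <- simulateRadiotracer(d1, noise = FALSE)
  expect_equal(b$samples$counts, a$samples$counts / 2)
  expect_equal(b$totals$counts, a$totals$counts / 2)
})

test_that("radiotracer expectation is non-decreasing before exhaustion; controls flat", {
  d <- RadiotracerDesign(rate = 1.5, dip = 30, times = seq(0, 18, 3),
                         countingDelayDays = 1)
  sim <- simulateRadiotracer(d, noise = FALSE)
  r1 <- sim$samples[sim$samples$bottle == "R1", "counts"]
  expect_true(all(diff(r1) >= 0))
  ctrl <- sim$samples[sim$samples$bottle == "control_killed", "counts"]
  expect_equal(diff(ctrl), rep(0, length(ctrl) - 1))
})

test_that("bulk incubation: zero rate gives natural abundance, excess is linear in t", {
  d0 <- BulkDesign(rateC = 0, rateN = 0)
  sim0 <- simulateBulkIncubation(d0)
  expect_equal(sim0$aEnd, sim0$aNa)
  d1 <- BulkDesign(durationH = 24, noiseSD = 0)
  d2 <- BulkDesign(durationH = 48, noiseSD = 0)
  e1 <- simulateBulkIncubation(d1)
  e2 <- simulateBulkIncubation(d2)
  expect_equal(e2$aEnd - e2$aNa, 2 * (e1$aEnd - e1$aNa), tolerance = 1e-12)
  expect_error(simulateBulkIncubation(BulkDesign(rateN = 1e5)),
               "exceeds the particulate pool")
})

test_that("colony scenario presets carry the study's condition parameters", {
  nod <- colonyScenario("nodularia", "in_situ", seed = 1)
  expect_equal(nod$truth$epiActN, 0.08)
  expect_equal(nod$truth$epiActC, 0.08)
  expect_equal(nod$truth$epiPerCell, 20)
  aph <- colonyScenario("aphanizomenon", "in_situ", seed = 1)
  expect_equal(aph$truth$epiActC, 0.03)
  expect_equal(aph$truth$epiPerCell, 2)
  expect_equal(sourceFraction(nod$conditions, "C"), 0.119)
  expect_equal(sourceFraction(nod$conditions, "N"), 0.018)
  expect_equal(incubationDays(nod$conditions), 1)
  expect_error(colonyScenario("nodularia", "no_such_condition"))
})

test_that("scenario activity draws are log-normal around the preset median", {
  actN <- unlist(lapply(1:30, function(s)
    colonyScenario("nodularia", "in_situ", nEpibionts = 40,
                   seed = s)$truth$cellActN))
  vols <- unlist(lapply(1:30, function(s)
    colonyScenario("nodularia", "in_situ", nEpibionts = 40,
                   seed = s)$truth$cellVolumes))
  expect_equal(median(actN), 0.08, tolerance = 0.05)
  expect_equal(sd(actN), 0.03, tolerance = 0.2)
  expect_equal(median(vols), 0.84, tolerance = 0.05)
})

test_that("scenario cells never overlap and an overfull field errors", {
  sc <- colonyScenario("nodularia", "in_situ", nEpibionts = 36,
                       imageSize = 128, seed = 9)
  sim <- simulateIonStack(sc$scene,
                          AcquisitionParams(128, 128, planes = 1), seed = 9)
  # every cell must appear in the mask with a plausible pixel area
  cells <- sceneCells(sc$scene)
  for (k in seq_len(nrow(cells))) {
    area <- sum(sim$mask == cells$id[k])
    expect_gt(area, 0.8 * pi * cells$a[k] * cells$b[k])
  }
  expect_error(colonyScenario("nodularia", "in_situ", nEpibionts = 4000),
               "field too small")
})
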
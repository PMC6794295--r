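test_that("a drift-free stack registers with all-zero offsets and is unchanged", {
  scene <- makeCellScene()
  sim <- simulateIonStack(scene, quickAcq(planes = 4), seed = 1)
  dc <- driftCorrect(sim$stack)
  expect_equal(dc$offsets, matrix(0L, 4, 2))
  expect_identical(dc$stack@counts, sim$stack@counts)
  expect_false(any(dc$flags$boundary))
})

test_that("known integer drifts are recovered exactly at realistic counts", {
  scene <- makeCellScene(radius = 8, size = 64, yieldCN = 20)
  drift <- cbind(c(0, 2, -3, 5, -5, 1), c(0, -1, 4, -5, 5, 0))
  sim <- simulateIonStack(scene, quickAcq(size = 64, planes = 6, drift = drift),
                          seed = 5)
  dc <- driftCorrect(sim$stack)
  expect_equal(dc$offsets, matrix(as.integer(drift), ncol = 2))
})

test_that("drift correction then accumulation equals the drift-free accumulation", {
  scene <- makeCellScene(radius = 6, size = 48, yieldCN = 15)
  drift <- cbind(c(0, 3, -2, 4), c(0, -4, 1, 2))
  drifted <- simulateIonStack(scene, quickAcq(planes = 4, drift = drift),
                              seed = 11)
  driftFree <- simulateIonStack(scene, quickAcq(planes = 4), seed = 11)
  accA <- accumulate(driftCorrect(drifted$stack)$stack)
  accB <- accumulate(driftFree$stack)
  for (sp in ionSpecies(drifted$stack))
    expect_identical(accA[[sp]], accB[[sp]])
})

test_that("a flat reference plane is reported as degenerate with offset (0,0)", {
  flat <- array(3, c(16, 16, 2))
  stk <- IonImageStack(list(`12C14N` = flat, `12C` = flat), pixelSize = 0.1)
  dc <- driftCorrect(stk, window = 4)
  expect_equal(dc$offsets[2, ], c(0L, 0L))
  expect_true(dc$flags$degenerate[2])
  empty <- array(0, c(16, 16, 2))
  expect_error(driftCorrect(IonImageStack(list(`12C14N` = empty),
                                          pixelSize = 0.1)),
               "empty reference plane")
})

test_that("accumulation sums planes and conserves counts", {
  a <- array(2, c(8, 8, 1))
  one <- accumulate(IonImageStack(list(`12C` = a), pixelSize = 0.1))
  expect_equal(one[["12C"]], a[, , 1])
  b <- array(3, c(8, 8, 40))
  forty <- accumulate(IonImageStack(list(`12C` = b), pixelSize = 0.1))
  expect_equal(forty[["12C"]], matrix(120, 8, 8))
  set.seed(1)
  r <- array(rpois(8 * 8 * 5, 4), c(8, 8, 5))
  acc <- accumulate(IonImageStack(list(`12C` = r), pixelSize = 0.1))
  expect_equal(sum(acc[["12C"]]), sum(r))
})

test_that("ROI ratios are exact on constant patches and flag degenerate counts", {
  img <- list(`13C` = matrix(0, 8, 8), `12C` = matrix(10, 8, 8),
              `12C14N` = matrix(50, 8, 8), `12C15N` = matrix(2, 8, 8))
  img$`13C`[1:4, ] <- 4
  mask <- matrix(0L, 8, 8); mask[1:4, ] <- 1L; mask[6:8, ] <- 2L
  m <- roiRatios(img, mask, pixelSize = 0.1)
  expect_equal(m$ratioC, c(4 / 10, 0))
  expect_true(m$lowCountC[2])       # zero minor counts: ratio 0, flagged
  expect_equal(m$ratioN, c(2 / 50, 2 / 50))
  # zero major counts invalidates the channel
  img$`12C`[, ] <- 0
  m2 <- roiRatios(img, mask, pixelSize = 0.1)
  expect_false(any(m2$validC))
  expect_true(all(is.na(m2$ratioC)))
})

test_that("ROI ratio recovers the true atom fraction within counting statistics", {
  # true A = 0.05 -> ratio 0.052631..., >= 1e4 major counts
  scene <- makeCellScene(atomC = 0.05, radius = 8, size = 48, yieldC = 60)
  sim <- simulateIonStack(scene, quickAcq(planes = 4), seed = 9)
  m <- roiRatios(accumulate(sim$stack), sim$mask)
  expect_gt(m$c12, 1e4)
  rTrue <- 0.05 / 0.95
  expect_lt(abs(m$ratioC - rTrue), 3 * m$seC)
})

test_that("ratio estimator is invariant under uniform count scaling", {
  img <- list(`13C` = matrix(3, 4, 4), `12C` = matrix(60, 4, 4))
  imgK <- list(`13C` = matrix(21, 4, 4), `12C` = matrix(420, 4, 4))
  mask <- matrix(1L, 4, 4)
  expect_equal(roiRatios(img, mask, pixelSize = 1)$ratioC,
               roiRatios(imgK, mask, pixelSize = 1)$ratioC)
})

test_that("counting SE shrinks as 1/sqrt(planes)", {
  planes <- c(4, 8, 16, 32, 64)
  ses <- vapply(planes, function(np) {
    img <- list(`13C` = matrix(5 * np, 6, 6), `12C` = matrix(95 * np, 6, 6))
    roiRatios(img, matrix(1L, 6, 6), pixelSize = 1)$seC
  }, 0)
  slope <- coef(lm(log(ses) ~ log(planes)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.05)
})

test_that("ellipse fit recovers cell length and width", {
  scene <- makeCellScene(radius = 10, size = 64)
  cells <- sceneCells(scene)
  cells$a <- 16; cells$b <- 8; cells$theta <- pi / 6
  cells$lengthUm <- 3.2; cells$widthUm <- 1.6
  scene2 <- ColonyScene(cells, background = c(C = 0, CN = 0, P = 0, S = 0),
                        pixelSize = 0.1)
  sim <- simulateIonStack(scene2, quickAcq(size = 64, planes = 1), seed = 1)
  m <- roiRatios(accumulate(sim$stack), sim$mask)
  expect_equal(m$lengthUm, 3.2, tolerance = 0.1)
  expect_equal(m$widthUm, 1.6, tolerance = 0.1)
})

test_that("detection limits use strict 'above' and match a brute-force filter", {
  m <- data.frame(ratioC = c(0.0117, 0.0118, 0.5, 0.002),
                  validC = c(TRUE, TRUE, TRUE, TRUE),
                  ratioN = c(0.0043, 0.0044, 0.001, NA),
                  validN = c(TRUE, TRUE, TRUE, FALSE))
  d <- applyDetectionLimits(m)
  expect_equal(d$measurements$retainedC, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(d$measurements$retainedN, c(FALSE, TRUE, FALSE, FALSE))
  set.seed(2)
  cohort <- data.frame(ratioC = rlnorm(500, log(0.012), 0.5), validC = TRUE,
                       ratioN = rlnorm(500, log(0.004), 0.6), validN = TRUE)
  d2 <- applyDetectionLimits(cohort)
  expect_equal(d2$summary$retained[1], sum(cohort$ratioC > 0.0117))
  expect_equal(d2$summary$retained[2], sum(cohort$ratioN > 0.0043))
})

test_that("segmentation proposes well-separated cells and handles blanks", {
  expect_equal(max(segmentEpibionts(list(`12C14N` = matrix(0, 16, 16)))), 0)
  centers <- cbind(c(12, 36, 52, 20, 44), c(12, 16, 44, 52, 36))
  scene <- makeCellScene(atomC = 0.02, radius = 4, centers = centers,
                         size = 64, yieldCN = 80)
  sim <- simulateIonStack(scene, quickAcq(size = 64, planes = 10), seed = 4)
  lab <- segmentEpibionts(accumulate(sim$stack))
  truth <- sim$mask
  recovered <- 0
  for (id in seq_len(nrow(centers))) {
    tpx <- truth == id
    best <- 0
    for (l in setdiff(unique(as.vector(lab[tpx])), 0)) {
      jac <- sum(tpx & lab == l) / sum(tpx | lab == l)
      best <- max(best, jac)
    }
    if (best >= 0.5) recovered <- recovered + 1
  }
  expect_gte(recovered / nrow(centers), 0.9)
})
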
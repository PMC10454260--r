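test_that("JMLE recovers generating item difficulties and thresholds", {
  exp <- recoveryExperiment()
  est <- modelParams(exp$fit)
  true <- exp$coh$params
  expect_true(est@fit$converged)
  expect_lte(sqrt(mean((itemDifficulties(est) -
                          itemDifficulties(true))^2)), 0.15)
  expect_lte(sqrt(mean((thresholds(est) - thresholds(true))^2)), 0.15)
  # identification invariants of the estimate
  expect_lt(abs(mean(itemDifficulties(est))), 1e-6)
  expect_lt(abs(sum(thresholds(est))), 1e-6)
})

test_that("items with identical response columns get identical difficulties", {
  coh <- simulateCohort(nPersons = 200, nItems = 6, seed = 5)
  sc <- scores(coh$baseline)
  sc[, 2] <- sc[, 1]  # clone an item
  fit <- fitRSM(ResponseMatrix(sc))
  d <- itemDifficulties(fit)
  expect_lt(abs(d[1] - d[2]), 1e-3)
})

test_that("degenerate inputs raise structured errors", {
  # every person extreme: nothing to estimate
  sc <- rbind(c(0, 0, 0), c(2, 2, 2), c(0, 0, 0), c(2, 2, 2))
  expect_error(fitRSM(ResponseMatrix(sc)), class = "cnc_no_estimable_items")
  # middle category never observed
  set.seed(2)
  sc2 <- matrix(sample(c(0L, 2L), 60, replace = TRUE), 10, 6)
  expect_error(fitRSM(ResponseMatrix(sc2)),
               class = "cnc_unobserved_category")
  expect_error(fitRSM(ResponseMatrix(sc2)), "category 1")
})

test_that("shifting all abilities leaves items invariant and shifts measures", {
  base <- simulateCohort(nPersons = 300, nItems = 8, changeMean = 0,
                         changeSD = 0, seed = 21)
  shift <- 0.8
  set.seed(99)
  shifted <- simulateCohort(nPersons = 300, nItems = 8, changeMean = 0,
                            changeSD = 0, thetaMean = -0.8 + shift, seed = 21)
  f1 <- fitRSM(base$baseline, biasCorrection = TRUE)
  f2 <- fitRSM(shifted$baseline, biasCorrection = TRUE)
  expect_lt(max(abs(itemDifficulties(f1) - itemDifficulties(f2))), 0.3)
  m1 <- personMeasures(f1); m2 <- personMeasures(f2)
  keep <- !m1$extreme & !m2$extreme
  expect_lt(abs(mean(m2$measure[keep] - m1$measure[keep]) - shift), 0.15)
})

test_that("raw score to measure inversion is exact and monotone", {
  p <- spreadParams(8)
  # symmetric case: the midpoint raw score maps to 0 logits
  expect_equal(personMeasureFromRaw(8, symmetricParams(8))$measure, 0,
               tolerance = 1e-6)
  pm <- personMeasureFromRaw(0:16, p)
  expect_true(all(diff(pm$measure) > 0))
  expect_true(all(pm$se > 0))
  expect_identical(pm$extreme, c(TRUE, rep(FALSE, 15), TRUE))
  # TCC round trip for non-extreme scores
  for (raw in 1:15)
    expect_equal(expectedScore(pm$measure[raw + 1], p), raw,
                 tolerance = 1e-6)
  # extreme scores invert to the adjusted target
  expect_equal(expectedScore(pm$measure[1], p), 0.3, tolerance = 1e-6)
  expect_equal(expectedScore(pm$measure[17], p), 15.7, tolerance = 1e-6)
  expect_error(personMeasureFromRaw(17, p), class = "cnc_invalid_argument")
})

test_that("conversion tables have one row per achievable total", {
  p8 <- spreadParams(8)
  ct8 <- conversionTable(p8)
  expect_identical(nrow(ct8), 17L)
  expect_true(all(diff(ct8$measure) > 0))
  expect_identical(ct8$original_total, as.integer(2 * (16 - 0:16)))
  p10 <- spreadParams(10)
  ct10 <- conversionTable(p10)
  expect_identical(nrow(ct10), 21L)
  expect_true(all(diff(ct10$measure) > 0))
  expect_identical(range(ct10$original_total), c(0L, 40L))
})

test_that("Wright person separation reliability behaves at its limits", {
  set.seed(7)
  meas <- rnorm(60, 0, 1.25)
  # error-free limit
  expect_gt(wrightPSR(meas, se = rep(1e-6, 60)), 0.999)
  # all-noise limit: mean squared SE equals observed variance
  v <- var(meas)
  expect_equal(wrightPSR(meas, se = rep(sqrt(v), 60)), 0)
  # analytic expectation at the published cohort scale
  set.seed(8)
  m2 <- rnorm(500, -0.6, 1.25) + rnorm(500, 0, 0.45)
  r <- wrightPSR(m2, se = rep(0.45, 500))
  expect_equal(r, (1.25^2 - 0.45^2) / 1.25^2, tolerance = 0.05)
  expect_error(wrightPSR(1.2, se = 0.4), class = "cnc_invalid_argument")
})
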
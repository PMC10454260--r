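test_that("cohort generation is reproducible and respects its config", {
  a <- simulateCohort(nPersons = 30, nItems = 8, seed = 4)
  b <- simulateCohort(nPersons = 30, nItems = 8, seed = 4)
  expect_identical(scores(a$baseline), scores(b$baseline))
  expect_identical(scores(a$followup), scores(b$followup))
  expect_identical(a$truth, b$truth)
  # no latent change: both timepoints share one ability vector
  noc <- simulateCohort(nPersons = 25, nItems = 8, changeMean = 0,
                        changeSD = 0, seed = 9)
  expect_identical(noc$truth$theta, noc$truth$theta_fu)
  expect_false(identical(scores(noc$baseline), scores(noc$followup)))
  # missingness keeps the matrix valid
  mis <- simulateCohort(nPersons = 30, nItems = 8, missingRate = 0.2,
                        seed = 10)
  expect_true(anyNA(scores(mis$baseline)))
  expect_true(methods::validObject(mis$baseline))
  expect_error(simulateCohort(nPersons = 1), class = "cnc_invalid_argument")
  expect_error(simulateCohort(missingRate = 1), class = "cnc_invalid_argument")
})

test_that("CNC rescoring reverses and compacts the 0/2/4 codes", {
  expect_equal(rescoreCNC(c(0, 2, 4)), c(2, 1, 0))
  expect_equal(rescoreCNC(c(4, NA, 0)), c(0, NA, 2))
  err <- tryCatch(rescoreCNC(c(0, 3, 4)), condition = identity)
  expect_s3_class(err, "cnc_invalid_value")
  expect_match(conditionMessage(err), "3")
  expect_match(conditionMessage(err), "position 2")
})

test_that("rescored totals map back to the published original-scale totals", {
  expect_identical(originalTotal(0, 8), 32L)
  expect_identical(originalTotal(16, 8), 0L)
  expect_identical(originalTotal(10, 10), 20L)
  expect_identical(originalTotal(0:16, 8), as.integer(seq(32, 0, by = -2)))
  expect_error(originalTotal(17, 8), class = "cnc_invalid_argument")
})

test_that("category frequencies converge to model-implied probabilities", {
  coh <- simulateCohort(nPersons = 5000, nItems = 8, changeMean = 0,
                        changeSD = 0, seed = 14)
  sc <- scores(coh$baseline)
  theta <- coh$truth$theta
  deltas <- itemDifficulties(coh$params)
  taus <- thresholds(coh$params)
  chisq <- 0
  for (i in seq_along(deltas)) {
    p <- categoryProbs(theta, deltas[i], taus)
    expcnt <- colSums(p)
    obs <- tabulate(sc[, i] + 1L, nbins = 3L)
    chisq <- chisq + sum((obs - expcnt)^2 / expcnt)
  }
  df <- length(deltas) * 2
  expect_gt(stats::pchisq(chisq, df, lower.tail = FALSE), 0.01)
})

test_that("the injected mean logit change is recovered after Rasch scoring", {
  coh <- simulateCohort(nPersons = 2000, nItems = 8, seed = 12)
  fit <- fitRSM(stackTimepoints(coh$baseline, coh$followup),
                biasCorrection = TRUE)
  paired <- pairMeasures(fit)
  expect_lt(abs(mean(paired$change) - 0.35), 0.1)
})
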
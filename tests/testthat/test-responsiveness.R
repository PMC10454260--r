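test_that("pooled SD follows the equal-n formula", {
  expect_equal(pooledSD(0.8, 0.8), 0.8, tolerance = 1e-12)
  expect_equal(round(pooledSD(1.4, 1.1), 3), 1.259)
  expect_equal(round(pooledSD(1.2, 1.0), 3), 1.105)
  expect_error(pooledSD(0, 1), class = "cnc_invalid_argument")
})

test_that("SEM, MDC95 and MCIDs reproduce the published panel values", {
  # 8-item panel: SD_pooled 1.25, r 0.87
  expect_equal(roundHalfUp(semMeasurement(1.25, 0.87)), 0.45)
  expect_equal(roundHalfUp(mdc95(0.45)), 1.25)
  expect_equal(roundHalfUp(distributionMCID(1.25, 0.20)), 0.25)
  expect_equal(roundHalfUp(distributionMCID(1.25, 0.33)), 0.41)
  expect_equal(roundHalfUp(distributionMCID(1.25, 0.50)), 0.63)
  # 10-item panel: SD_pooled 1.12, r 0.89
  expect_equal(roundHalfUp(semMeasurement(1.12, 0.89)), 0.37)
  expect_equal(roundHalfUp(mdc95(0.37)), 1.03)
  expect_equal(roundHalfUp(distributionMCID(1.12, 0.20)), 0.22)
  expect_equal(roundHalfUp(distributionMCID(1.12, 0.33)), 0.37)
  expect_equal(roundHalfUp(distributionMCID(1.12, 0.50)), 0.56)
  # limits and argument checks
  expect_equal(semMeasurement(1.3, 0), 1.3)
  expect_equal(mdc95(0), 0)
  expect_error(semMeasurement(1.25, 1), class = "cnc_invalid_argument")
  expect_error(distributionMCID(1.25, 1.5), class = "cnc_invalid_argument")
})

test_that("effect size, its CI and the SRM follow their definitions", {
  expect_equal(roundHalfUp(effectSize(-0.72, -0.43, 1.12)), 0.26)
  expect_equal(round(effectSize(-0.80, -0.43, 1.25), 3), 0.296)
  expect_equal(effectSize(1.1, 1.1, 0.7), 0)
  ci <- effectSizeCI(0.29, 40)
  expect_lte(ci["lower"], 0.29); expect_gte(ci["upper"], 0.29)
  expect_lt(max(abs(unname(ci) - c(-0.02, 0.61))), 0.01)
  wide <- effectSizeCI(0, 1e8)
  expect_lt(wide["upper"] - wide["lower"], 1e-3)
  expect_equal(standardizedResponseMean(c(0.2, 0.4, 0.6)), 2.0)
  expect_equal(standardizedResponseMean(c(0.3, 0.5, 0.7)), 0.5 / sd(c(0.3, 0.5, 0.7)))
  expect_equal(standardizedResponseMean(c(1, -1)), 0)
  expect_error(standardizedResponseMean(c(0.5, 0.5, 0.5)),
               class = "cnc_zero_variance")
})

test_that("individual change classification respects the MDC boundary", {
  expect_identical(as.character(classifyChange(1.30, 1.25)), "improved")
  expect_identical(as.character(classifyChange(-1.30, 1.25)), "declined")
  expect_identical(as.character(classifyChange(1.25, 1.25)), "within_error")
  expect_identical(as.character(classifyChange(-1.25, 1.25)), "within_error")
  # antisymmetry over random changes
  set.seed(3)
  ch <- rnorm(200, 0, 1.5)
  a <- classifyChange(ch, 1.25)
  b <- classifyChange(-ch, 1.25)
  expect_identical(a == "improved", b == "declined")
  expect_identical(a == "within_error", b == "within_error")
})

test_that("change summaries equal a brute-force recount", {
  paired <- data.frame(person_id = 1:3, baseline = c(0, 1, 0.4),
                       followup = c(2, -1, 0.5),
                       change = c(2.0, -2.0, 0.1))
  s <- summarizeChange(paired, 1.25)
  expect_identical(unname(s$counts),
                   c(1L, 1L, 1L))
  set.seed(31)
  ch <- rnorm(40, 0.35, 1.0)
  s2 <- summarizeChange(data.frame(change = ch), 1.25)
  expect_identical(s2$beyond_error, sum(abs(ch) > 1.25))
  expect_identical(unname(s2$counts["improved"]), sum(ch > 1.25))
  expect_identical(unname(s2$counts["declined"]), sum(ch < -1.25))
  expect_equal(sum(s2$proportions), 1)
  zero <- summarizeChange(data.frame(change = rep(0, 5)), 1.25)
  expect_identical(unname(zero$counts[c("improved", "declined")]), c(0L, 0L))
  expect_identical(unname(zero$counts["within_error"]), 5L)
})

test_that("worked clinical quantities: ability band and true-change threshold", {
  expect_equal(unname(measureBand(-1.86, 0.45)), c(-2.31, -1.41))
  expect_equal(unname(measureBand(0, 0.3)), c(-0.3, 0.3))
  expect_equal(trueChangeThreshold(-1.86, 1.25, "improvement"), -0.61)
  expect_equal(trueChangeThreshold(0, 1.25, "decline"), -1.25)
  expect_equal(trueChangeThreshold(0.4, 0.9, "improvement") -
                 trueChangeThreshold(0.4, 0.9, "decline"), 1.8)
})

test_that("the assembled panel is internally consistent and matches print", {
  idx8 <- responsivenessFromSummary(n = 40, meanBl = -0.80, meanFu = -0.43,
                                    sdBl = 1.4, sdFu = 1.1, r = 0.87,
                                    sdPooled = 1.25)
  expect_equal(roundHalfUp(idx8@sem), 0.45)
  expect_equal(roundHalfUp(idx8@mdc95), 1.25)
  expect_equal(roundHalfUp(idx8@mcid033), 0.41)
  expect_equal(roundHalfUp(idx8@mcid050), 0.63)
  idx10 <- responsivenessFromSummary(n = 40, meanBl = -0.72, meanFu = -0.43,
                                     r = 0.89, sdPooled = 1.12)
  expect_equal(roundHalfUp(idx10@sem), 0.37)
  expect_equal(roundHalfUp(idx10@mdc95), 1.03)
  expect_equal(roundHalfUp(idx10@mcid050), 0.56)
  expect_equal(roundHalfUp(idx10@effectSize), 0.26)
  rep10 <- reportIndices(idx10)
  expect_identical(rep10$`MDC_95`, 1.03)
  expect_identical(rep10$`MCID 0.33 SD`, 0.37)
})

test_that("panel from person-level pairs obeys scale equivariance", {
  set.seed(12)
  paired <- data.frame(person_id = 1:50, baseline = rnorm(50, -0.8, 1.3))
  paired$followup <- paired$baseline + rnorm(50, 0.4, 0.8)
  paired$change <- paired$followup - paired$baseline
  idx <- computeIndices(paired, r = 0.87)
  # mdc95 dominates the medium MCID whenever r < 0.967
  expect_gt(idx@mdc95, idx@mcid050)
  expect_true(idx@mcid020 < idx@mcid033 && idx@mcid033 < idx@mcid050)
  for (sf in c(0.5, 2, 7)) {
    sc <- paired
    sc$baseline <- sc$baseline * sf
    sc$followup <- sc$followup * sf
    sc$change <- sc$followup - sc$baseline
    idxs <- computeIndices(sc, r = 0.87)
    expect_equal(idxs@sdPooled, sf * idx@sdPooled, tolerance = 1e-10)
    expect_equal(idxs@sem, sf * idx@sem, tolerance = 1e-10)
    expect_equal(idxs@mdc95, sf * idx@mdc95, tolerance = 1e-10)
    expect_equal(idxs@mcid033, sf * idx@mcid033, tolerance = 1e-10)
    expect_equal(idxs@meanChange, sf * idx@meanChange, tolerance = 1e-10)
    expect_equal(idxs@effectSize, idx@effectSize, tolerance = 1e-10)
    expect_equal(idxs@srm, idx@srm, tolerance = 1e-10)
  }
  # ordering holds across random panels with r below the crossover
  set.seed(13)
  for (i in 1:50) {
    r <- runif(1, 0, 0.96)
    sdp <- runif(1, 0.2, 3)
    expect_gt(mdc95(semMeasurement(sdp, r)), distributionMCID(sdp, 0.50))
  }
})
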
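# shared simulated cohorts; computed once per test run
.cohortCache <- new.env(parent = emptyenv())

# n = 500 persons, 8 items, stacked two-timepoint calibration used by the
# parameter-recovery and end-to-end checks
recoveryExperiment <- function() {
  if (is.null(.cohortCache$recovery)) {
    coh <- simulateCohort(nPersons = 500, nItems = 8, seed = 11)
    fit <- fitRSM(stackTimepoints(coh$baseline, coh$followup),
                  biasCorrection = TRUE)
    .cohortCache$recovery <- list(coh = coh, fit = fit)
  }
  .cohortCache$recovery
}

symmetricParams <- function(L = 8, taus = c(-1, 1))
  RSMParams(rep(0, L), taus)

spreadParams <- function(L = 8, taus = c(-1, 1))
  RSMParams(seq(-1, 1, length.out = L), taus)

# independent evaluation of the shared-threshold partial credit formula,
# written as literal cumulative sums (oracle for categoryProbs)
pcmOracle <- function(theta, delta, taus) {
  m <- length(taus)
  num <- numeric(m + 1)
  num[1] <- exp(0)
  for (k in 1:m) {
    s <- 0
    for (j in 1:k) s <- s + (theta - delta - taus[j])
    num[k + 1] <- exp(s)
  }
  num / sum(num)
}
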
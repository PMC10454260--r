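#' Category probabilities of the rating scale model
#'
#' Probability of each response category for a person of ability
#' \code{theta} on an item of difficulty \code{delta}, under the Andrich
#' rating scale model with shared thresholds \code{taus}:
#' \deqn{P(X = k) \propto \exp\!\Big(\sum_{j=1}^{k} (\theta - \delta - \tau_j)\Big)}
#' with the empty sum (1) for category 0.
#'
#' @param theta person ability in logits (may be a vector).
#' @param delta item difficulty in logits (scalar).
#' @param taus numeric vector of category thresholds (length = number of
#'   categories minus one).
#' @return for scalar \code{theta} a probability vector of length
#'   \code{length(taus) + 1}; for vector \code{theta} a matrix with one row
#'   per ability.
#' @examples
#' categoryProbs(0, 0, c(0, 0))    # uniform 1/3
#' categoryProbs(1, 0, c(-1, 1))
#' @export
categoryProbs <- function(theta, delta, taus) {
  .assertFiniteScalar(theta, "theta")
  .assertFiniteScalar(delta, "delta")
  .assertFiniteScalar(taus, "taus")
  if (length(delta) != 1L)
    .stopCNC("cnc_invalid_argument", "'delta' must be a single difficulty")
  m <- length(taus)
  k <- 0:m
  # log numerator: k*(theta - delta) - cumsum(tau)_k, stabilised by max
  cumtau <- c(0, cumsum(taus))
  eta <- outer(theta - delta, k) - rep(cumtau, each = length(theta))
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta)
  p <- p / rowSums(p)
  if (length(theta) == 1L) drop(p) else p
}

# cell-level probabilities for all persons x items at once.
# returns list of (m+1) matrices [n x L]; the workhorse of estimation.
.cellProbs <- function(theta, deltas, taus) {
  m <- length(taus)
  cumtau <- c(0, cumsum(taus))
  d <- outer(theta, deltas, "-")        # n x L, theta - delta
  mats <- vector("list", m + 1L)
  for (k in 0:m) mats[[k + 1L]] <- k * d - cumtau[k + 1L]
  mx <- Reduce(pmax, mats)
  tot <- 0
  for (k in 0:m) {
    mats[[k + 1L]] <- exp(mats[[k + 1L]] - mx)
    tot <- tot + mats[[k + 1L]]
  }
  for (k in 0:m) mats[[k + 1L]] <- mats[[k + 1L]] / tot
  mats
}

# expected cell score and variance from .cellProbs output
.cellMoments <- function(probs) {
  m <- length(probs) - 1L
  E <- 0; E2 <- 0
  for (k in seq_len(m)) {
    E <- E + k * probs[[k + 1L]]
    E2 <- E2 + k * k * probs[[k + 1L]]
  }
  list(E = E, V = E2 - E * E)
}

.paramsItems <- function(params, items) {
  deltas <- itemDifficulties(params)
  if (is.null(items)) return(deltas)
  deltas <- deltas[items]
  if (length(deltas) == 0L || anyNA(deltas))
    .stopCNC("cnc_invalid_argument", "empty or unknown item subset")
  deltas
}

#' Expected raw score (test characteristic curve)
#'
#' Expected total rescored score for a person of ability \code{theta} over a
#' set of items: the test characteristic curve whose inverse yields the raw
#' score-to-measure conversion.
#'
#' @param theta ability in logits (vectorised).
#' @param params an [RSMParams-class] object.
#' @param items optional item subset (indices or names); default all items.
#' @return expected raw score(s), strictly increasing in \code{theta} from 0
#'   to \code{m * L}.
#' @examples
#' p <- RSMParams(rep(0, 8), c(0, 0))
#' expectedScore(0, p)  # 8: each item expects m/2 = 1 by symmetry
#' @export
expectedScore <- function(theta, params, items = NULL) {
  .assertFiniteScalar(theta, "theta")
  deltas <- .paramsItems(params, items)
  mom <- .cellMoments(.cellProbs(theta, deltas, thresholds(params)))
  unname(rowSums(mom$E))
}

#' Test information
#'
#' Fisher information of the total score at ability \code{theta}: the sum of
#' item score variances.  The model-based standard error of a person measure
#' is \code{1 / sqrt(testInformation(theta, ...))}.
#'
#' @inheritParams expectedScore
#' @return information (1/logits^2), vectorised over \code{theta}.
#' @export
testInformation <- function(theta, params, items = NULL) {
  .assertFiniteScalar(theta, "theta")
  deltas <- .paramsItems(params, items)
  mom <- .cellMoments(.cellProbs(theta, deltas, thresholds(params)))
  unname(rowSums(mom$V))
}
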
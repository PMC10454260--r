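#' Fit the rating scale model by joint maximum likelihood
#'
#' Estimates item difficulties, shared category thresholds and person
#' measures from a [ResponseMatrix-class] by JMLE: PROX-style starting
#' values, then alternating damped Newton-Raphson updates of persons, items
#' and thresholds until the largest parameter update falls below \code{tol}.
#' Persons with extreme raw scores (0 or the maximum over their answered
#' items) are excluded from item/threshold estimation and afterwards receive
#' finite extrapolated measures via [personMeasureFromRaw()].  Items are
#' centered at mean difficulty 0 and thresholds at sum 0; the person scale
#' is otherwise free.
#'
#' @param x a [ResponseMatrix-class]; two timepoints can be stacked with
#'   [stackTimepoints()] for a single calibration.
#' @param tol convergence tolerance: largest absolute parameter update in
#'   logits (default 1e-4).
#' @param maxIter maximum number of alternating sweeps (default 200).
#' @param biasCorrection logical; multiply the estimated item difficulties
#'   and thresholds by \code{(L-1)/L} to counter the well-known outward JMLE
#'   bias.  Off by default, matching common rating-scale software practice.
#' @param extremeAdjust score-point adjustment pulling extreme raw scores
#'   inward before measure extrapolation (default 0.3).
#' @param verbose print iteration progress.
#' @return an [RSMFit-class] with accessors [modelParams()] and
#'   [personMeasures()].  Non-convergence within \code{maxIter} produces a
#'   warning and \code{converged = FALSE} in the fit metadata.
#' @examples
#' set.seed(1)
#' coh <- simulateCohort(nPersons = 60, nItems = 8, seed = 7)
#' fit <- fitRSM(coh$baseline)
#' itemDifficulties(fit)
#' head(personMeasures(fit))
#' @export
fitRSM <- function(x, tol = 1e-4, maxIter = 200L, biasCorrection = FALSE,
                   extremeAdjust = 0.3, verbose = FALSE) {
  stopifnot(methods::is(x, "ResponseMatrix"))
  methods::validObject(x)
  sc <- scores(x)
  m <- nCategories(x) - 1L
  mask <- !is.na(sc)

  raw <- rowSums(sc * mask, na.rm = TRUE)
  maxp <- m * rowSums(mask)
  extreme <- raw == 0 | raw == maxp
  est <- which(!extreme)
  if (length(est) < 2L)
    .stopCNC("cnc_no_estimable_items",
             "all persons have extreme raw scores; no estimable items")
  escM <- sc[est, , drop = FALSE]
  emask <- mask[est, , drop = FALSE]
  if (any(colSums(emask) == 0L))
    .stopCNC("cnc_no_estimable_items",
             "an item has no responses from non-extreme persons")
  obs <- table(factor(escM[emask], levels = 0:m))
  if (any(obs == 0L)) {
    k <- as.integer(names(obs))[which(obs == 0L)[1L]]
    .stopCNC("cnc_unobserved_category",
             "category %d is never observed; thresholds are not estimable", k)
  }

  # PROX-flavoured starting values from logit-transformed proportions
  pr <- .clamp(raw[est] / maxp[est], 0.02, 0.98)
  theta <- log(pr / (1 - pr))
  sitem <- colSums(escM * emask, na.rm = TRUE)
  mitem <- m * colSums(emask)
  pi <- .clamp(sitem / mitem, 0.02, 0.98)
  deltas <- -log(pi / (1 - pi))
  deltas <- deltas - mean(deltas)
  cnt <- as.numeric(table(factor(escM[emask], levels = 0:m)))
  taus <- log(pmax(cnt[1:m], 0.5) / pmax(cnt[2:(m + 1L)], 0.5))
  taus <- taus - mean(taus)

  r_est <- raw[est]
  cge <- vapply(1:m, function(j) sum(escM[emask] >= j), numeric(1))
  eps <- 1e-9
  maxUpd <- Inf
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    # persons
    mom <- .cellMoments(.cellProbs(theta, deltas, taus))
    dTheta <- .clamp((r_est - rowSums(mom$E * emask)) /
                       pmax(rowSums(mom$V * emask), eps), -1, 1)
    theta <- theta + dTheta
    # items
    mom <- .cellMoments(.cellProbs(theta, deltas, taus))
    dDelta <- .clamp((colSums(mom$E * emask) - sitem) /
                       pmax(colSums(mom$V * emask), eps), -1, 1)
    deltas <- deltas + dDelta
    # thresholds: match observed counts of X >= j
    probs <- .cellProbs(theta, deltas, taus)
    dTau <- numeric(m)
    Pge <- 0
    for (j in m:1) {
      Pge <- Pge + probs[[j + 1L]]
      f <- sum(Pge[emask]) - cge[j]
      denom <- sum((Pge * (1 - Pge))[emask])
      dTau[j] <- .clamp(f / pmax(denom, eps), -1, 1)
    }
    taus <- taus + dTau
    # re-identify: thresholds sum 0 (absorbed by items), items mean 0
    # (absorbed by persons); the likelihood is invariant to both shifts
    mt <- mean(taus); taus <- taus - mt; deltas <- deltas + mt
    md <- mean(deltas); deltas <- deltas - md; theta <- theta - md
    maxUpd <- max(abs(dTheta), abs(dDelta), abs(dTau))
    if (verbose)
      message(sprintf("iter %3d  max update %.2e", iter, maxUpd))
    if (maxUpd < tol) break
  }
  converged <- maxUpd < tol
  if (!converged)
    warning(sprintf(
      "JMLE did not converge in %d iterations (max update %.2e)",
      maxIter, maxUpd), call. = FALSE)

  if (biasCorrection) {
    L <- ncol(sc)
    deltas <- (deltas - mean(deltas)) * (L - 1) / L
    taus <- taus * (L - 1) / L
  }

  params <- RSMParams(deltas = stats::setNames(deltas, colnames(sc)),
                      taus = taus,
                      fit = list(iterations = iter, maxUpdate = maxUpd,
                                 converged = converged))

  persons <- .measureAll(sc, mask, params, extremeAdjust)
  persons <- data.frame(person_id = x@meta$person_id,
                        timepoint = x@meta$timepoint,
                        persons, row.names = NULL,
                        stringsAsFactors = FALSE)
  methods::new("RSMFit", params = params, persons = persons, data = x)
}

# measure every row of a score matrix given fitted params; groups rows by
# (raw score, response pattern of answered items) so complete data costs one
# Newton solve per distinct raw score.
.measureAll <- function(sc, mask, params, extremeAdjust) {
  m <- nCategories(params) - 1L
  raw <- rowSums(sc * mask, na.rm = TRUE)
  maxp <- m * rowSums(mask)
  key <- paste(raw, apply(mask, 1L, function(z) paste(which(z), collapse = ",")))
  measure <- se <- numeric(nrow(sc))
  for (k in unique(key)) {
    idx <- which(key == k)
    i <- idx[1L]
    pm <- personMeasureFromRaw(raw[i], params, items = which(mask[i, ]),
                               extremeAdjust = extremeAdjust)
    measure[idx] <- pm$measure
    se[idx] <- pm$se
  }
  data.frame(raw_score = as.integer(raw), max_score = as.integer(maxp),
             measure = measure, se = se, extreme = raw == 0 | raw == maxp)
}

#' Person measure from a raw score
#'
#' Inverts the test characteristic curve: solves
#' \code{expectedScore(theta) = raw} by Newton-Raphson for the logit measure
#' corresponding to a total rescored raw score, with extreme scores (0 or the
#' maximum) pulled inward by \code{extremeAdjust} score points so that they
#' receive finite extrapolated measures.  The raw score is sufficient for
#' ability in the Rasch model, so the measure depends on the data only
#' through it.
#'
#' @param raw total rescored raw score(s), in \code{0..m*L} (vectorised).
#' @param params an [RSMParams-class].
#' @param items optional item subset defining the test the score was earned
#'   on; default all items.
#' @param extremeAdjust inward adjustment in score points applied to extreme
#'   raw scores before inversion (default 0.3).
#' @return data.frame with columns \code{raw}, \code{measure} (logits),
#'   \code{se} (logits, \code{1/sqrt(information)}), \code{extreme}.
#' @examples
#' p <- RSMParams(rep(0, 8), c(-1, 1))
#' personMeasureFromRaw(8, p)   # symmetric midpoint: measure 0
#' @export
personMeasureFromRaw <- function(raw, params, items = NULL,
                                 extremeAdjust = 0.3) {
  deltas <- .paramsItems(params, items)
  taus <- thresholds(params)
  m <- length(taus)
  top <- m * length(deltas)
  if (any(!is.finite(raw)) || any(raw < 0) || any(raw > top))
    .stopCNC("cnc_invalid_argument",
             "raw score must lie in [0, %d]", top)
  extreme <- raw == 0 | raw == top
  target <- ifelse(raw == 0, extremeAdjust,
                   ifelse(raw == top, top - extremeAdjust, raw))
  out <- vapply(target, function(tg) {
    theta <- 0
    for (it in 1:200) {
      mom <- .cellMoments(.cellProbs(theta, deltas, taus))
      E <- sum(mom$E); V <- max(sum(mom$V), 1e-12)
      step <- .clamp((tg - E) / V, -3, 3)
      theta <- theta + step
      if (abs(step) < 1e-11) break
    }
    info <- max(sum(.cellMoments(.cellProbs(theta, deltas, taus))$V), 1e-12)
    c(theta, 1 / sqrt(info))
  }, numeric(2))
  data.frame(raw = raw, measure = out[1L, ], se = out[2L, ],
             extreme = extreme)
}

#' Raw score-to-measure conversion table
#'
#' One row for every achievable rescored total from 0 to \code{m * L}, with
#' the corresponding logit measure and model SE, plus the equivalent total on
#' the original CNC 0/2/4 coding (where lower means better function):
#' \code{original_total = 2 * (m*L - rescored_total)}.
#'
#' @param params an [RSMParams-class].
#' @param nItems number of items L in the scale version (CNC: 8 or 10);
#'   defaults to the number of fitted items.
#' @param extremeAdjust passed to [personMeasureFromRaw()].
#' @return data.frame with columns \code{rescored_total},
#'   \code{original_total}, \code{measure}, \code{se}; measures strictly
#'   increase with the rescored total.
#' @examples
#' p <- RSMParams(seq(-1, 1, length.out = 8), c(-1, 1))
#' conversionTable(p)   # 17 rows for an 8-item, 3-category scale
#' @export
conversionTable <- function(params, nItems = length(itemDifficulties(params)),
                            extremeAdjust = 0.3) {
  L <- as.integer(nItems)
  deltas <- itemDifficulties(params)
  if (L > length(deltas))
    .stopCNC("cnc_invalid_argument",
             "nItems exceeds the number of fitted items")
  items <- seq_len(L)
  m <- nCategories(params) - 1L
  tot <- 0:(m * L)
  pm <- personMeasureFromRaw(tot, params, items = items,
                             extremeAdjust = extremeAdjust)
  out <- data.frame(rescored_total = tot,
                    original_total = originalTotal(tot, L),
                    measure = pm$measure, se = pm$se)
  stopifnot(all(diff(out$measure) > 0))
  out
}

#' Wright's person separation reliability
#'
#' The Rasch analogue of internal-consistency reliability:
#' \deqn{R = (Var_{obs} - \overline{SE^2}) / Var_{obs}} where
#' \eqn{Var_{obs}} is the observed variance of the included person measures
#' and \eqn{\overline{SE^2}} the mean squared model standard error.  Floored
#' at 0.  Persons with extreme raw scores are excluded by default, since
#' their measures are extrapolations with inflated SEs.
#'
#' @param measures an [RSMFit-class], the data.frame returned by
#'   [personMeasures()], or a numeric vector of measures.
#' @param se numeric vector of standard errors (required when
#'   \code{measures} is a bare numeric vector).
#' @param extreme optional logical vector flagging extreme persons.
#' @param includeExtreme keep extreme persons in the computation.
#' @return reliability in \code{[0, 1)}.
#' @examples
#' wrightPSR(rnorm(50, 0, 1.25), se = rep(0.45, 50))
#' @export
wrightPSR <- function(measures, se = NULL, extreme = NULL,
                      includeExtreme = FALSE) {
  if (methods::is(measures, "RSMFit")) measures <- personMeasures(measures)
  if (is.data.frame(measures)) {
    se <- measures$se
    extreme <- measures$extreme
    measures <- measures$measure
  }
  if (is.null(se) || length(se) != length(measures))
    .stopCNC("cnc_invalid_argument",
             "need one standard error per person measure")
  if (is.null(extreme)) extreme <- rep(FALSE, length(measures))
  keep <- if (includeExtreme) rep(TRUE, length(measures)) else !extreme
  if (sum(keep) < 2L)
    .stopCNC("cnc_invalid_argument",
             "need at least 2 included persons for reliability")
  v <- stats::var(measures[keep])
  if (v <= 0) return(0)
  max(0, (v - mean(se[keep]^2)) / v)
}
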
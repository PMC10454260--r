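#' Simulate a two-timepoint CNC-like cohort
#'
#' Draws a cohort from the rating scale model: baseline abilities
#' \eqn{\theta_n \sim N(\mu_\theta, \sigma_\theta)}, additive latent change
#' \eqn{\Delta_n \sim N(\mu_\Delta, \sigma_\Delta)} independent of baseline,
#' and item responses sampled from [categoryProbs()] at each timepoint.
#' Defaults emulate a disorders-of-consciousness cohort observed two weeks
#' apart: baseline mean -0.8 logits with SD 1.25 and a mean improvement of
#' 0.35 logits.
#'
#' @param nPersons cohort size (>= 2); the motivating study design has 40.
#' @param nItems number of items (CNC versions: 8 without or 10 with the
#'   pain items).
#' @param nCategories ordered categories per item (CNC rescored: 3).
#' @param thetaMean,thetaSD baseline ability distribution (logits).
#' @param changeMean,changeSD latent change distribution (logits);
#'   \code{changeSD = 0} reuses the baseline abilities at follow-up.
#' @param deltas item difficulties (logits); either an explicit vector of
#'   length \code{nItems} (centered on use) or \code{NULL} to space items
#'   evenly over \code{[-deltaSpread/2, deltaSpread/2]}.
#' @param deltaSpread width of the default evenly spaced difficulty range
#'   (logits).
#' @param taus category thresholds (logits, centered on use); default
#'   \code{c(-1, 1)}.
#' @param missingRate probability that any single response is missing
#'   completely at random, in \code{[0, 1)}.
#' @param seed integer seed; required for reproducibility of the draw.
#' @return list with elements \code{baseline} and \code{followup}
#'   ([ResponseMatrix-class] objects), \code{truth} (data.frame of
#'   per-person \code{theta}, \code{change}, \code{theta_fu}), and
#'   \code{params} (the generating [RSMParams-class]).
#' @examples
#' coh <- simulateCohort(nPersons = 40, nItems = 8, seed = 42)
#' coh$baseline
#' @export
simulateCohort <- function(nPersons = 40L, nItems = 8L, nCategories = 3L,
                           thetaMean = -0.8, thetaSD = 1.25,
                           changeMean = 0.35, changeSD = 0.9,
                           deltas = NULL, deltaSpread = 2, taus = c(-1, 1),
                           missingRate = 0, seed = NULL) {
  if (nPersons < 2L || nItems < 2L)
    .stopCNC("cnc_invalid_argument", "need >= 2 persons and >= 2 items")
  if (thetaSD <= 0 || changeSD < 0)
    .stopCNC("cnc_invalid_argument", "thetaSD must be > 0 and changeSD >= 0")
  if (missingRate < 0 || missingRate >= 1)
    .stopCNC("cnc_invalid_argument", "missingRate must lie in [0, 1)")
  if (length(taus) != nCategories - 1L)
    .stopCNC("cnc_invalid_argument", "need nCategories - 1 thresholds")
  if (is.null(deltas)) {
    deltas <- seq(-deltaSpread / 2, deltaSpread / 2, length.out = nItems)
  } else if (length(deltas) != nItems) {
    .stopCNC("cnc_invalid_argument", "need one difficulty per item")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  params <- RSMParams(deltas, taus)

  theta <- stats::rnorm(nPersons, thetaMean, thetaSD)
  change <- if (changeSD > 0 || changeMean != 0)
    stats::rnorm(nPersons, changeMean, changeSD) else rep(0, nPersons)
  ids <- sprintf("P%03d", seq_len(nPersons))

  m <- nCategories - 1L
  drawMatrix <- function(ab) {
    p <- .cellProbs(ab, itemDifficulties(params), thresholds(params))
    u <- matrix(stats::runif(nPersons * nItems), nPersons, nItems)
    sc <- matrix(0L, nPersons, nItems)
    cum <- p[[1L]]
    for (k in seq_len(m)) {
      sc <- sc + (u >= cum)
      cum <- cum + p[[k + 1L]]
    }
    if (missingRate > 0) {
      drop <- matrix(stats::runif(nPersons * nItems) < missingRate,
                     nPersons, nItems)
      # keep at least one response per person and per item
      for (i in seq_len(nPersons))
        if (all(drop[i, ])) drop[i, sample.int(nItems, 1L)] <- FALSE
      for (j in seq_len(nItems))
        if (all(drop[, j])) drop[sample.int(nPersons, 1L), j] <- FALSE
      sc[drop] <- NA_integer_
    }
    dimnames(sc) <- list(ids, names(itemDifficulties(params)))
    sc
  }

  baseline <- ResponseMatrix(drawMatrix(theta), nCategories = nCategories,
                             timepoint = "baseline")
  followup <- ResponseMatrix(drawMatrix(theta + change),
                             nCategories = nCategories,
                             timepoint = "followup")
  list(baseline = baseline, followup = followup,
       truth = data.frame(person_id = ids, theta = theta, change = change,
                          theta_fu = theta + change,
                          stringsAsFactors = FALSE),
       params = params)
}

#' Rescore original CNC item codes
#'
#' The CNC scoring form codes each item 0/2/4 with lower values indicating
#' better neurobehavioral function.  Analysis uses the reversed, compacted
#' coding 0/1/2 where higher is better: 0 -> 2, 2 -> 1, 4 -> 0.
#'
#' @param x numeric vector/matrix of original codes in \code{{0, 2, 4}};
#'   \code{NA} passes through.
#' @return object of the same shape with rescored values in \code{{0, 1, 2}}.
#' @examples
#' rescoreCNC(c(0, 2, 4))  # 2 1 0
#' @export
rescoreCNC <- function(x) {
  v <- x[!is.na(x)]
  bad <- which(!(v %in% c(0, 2, 4)))
  if (length(bad)) {
    cell <- which(!is.na(x))[bad[1L]]
    .stopCNC("cnc_invalid_value",
             "invalid original CNC code %s at position %d (allowed: 0, 2, 4)",
             format(v[bad[1L]]), cell)
  }
  out <- (4 - x) / 2
  out
}

#' Map a rescored total back to the original CNC total
#'
#' Rescored item scores are \code{(4 - original)/2}, so a rescored total
#' \code{t} over \code{L} items corresponds to an original-scale total of
#' \code{2 * (2L - t)} (original coding: lower = better function).
#'
#' @param rescoredTotal total rescored score(s) in \code{0..2L}.
#' @param nItems number of items L.
#' @return original-scale total(s) in \code{0..4L}.
#' @examples
#' originalTotal(0, 8)   # 32
#' originalTotal(16, 8)  # 0
#' @export
originalTotal <- function(rescoredTotal, nItems) {
  if (any(rescoredTotal < 0) || any(rescoredTotal > 2 * nItems) ||
      anyNA(rescoredTotal))
    .stopCNC("cnc_invalid_argument",
             "rescored total must lie in [0, %d]", 2 * nItems)
  as.integer(2 * (2 * nItems - rescoredTotal))
}
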
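#' @import methods
NULL

#' Person-by-item ordinal response matrix
#'
#' Container for rescored Coma/Near-Coma (CNC) style assessment data: one row
#' per person (or person-timepoint when stacked), one column per item, each
#' cell an integer category score in \code{0..(nCategories - 1)} or \code{NA}
#' for a skipped item.  On the rescored CNC convention a higher category means
#' better neurobehavioral function.
#'
#' @slot scores integer matrix of category scores with person ids as rownames
#'   and item ids as colnames; \code{NA} marks a missing response.
#' @slot nCategories integer, number of ordered categories (CNC: 3).
#' @slot meta data.frame with one row per row of \code{scores}; columns
#'   \code{person_id} and \code{timepoint} (used when two assessments are
#'   stacked into one calibration).
#'
#' @seealso [ResponseMatrix()] for the constructor, [fitRSM()].
#' @export
setClass("ResponseMatrix",
         slots = c(scores = "matrix", nCategories = "integer",
                   meta = "data.frame"))

setValidity("ResponseMatrix", function(object) {
  sc <- object@scores
  m <- object@nCategories - 1L
  if (length(object@nCategories) != 1L || object@nCategories < 2L)
    return("nCategories must be a single integer >= 2")
  if (!is.numeric(sc))
    return("scores must be a numeric/integer matrix")
  if (nrow(sc) < 2L || ncol(sc) < 2L)
    return("need at least 2 persons and 2 items")
  v <- sc[!is.na(sc)]
  if (length(v) == 0L)
    return("all scores are missing")
  if (any(v != round(v)) || any(v < 0L) || any(v > m))
    return(sprintf("scores must be integers in [0, %d] or NA", m))
  if (any(rowSums(!is.na(sc)) == 0L))
    return("every person needs at least one non-missing score")
  if (any(colSums(!is.na(sc)) == 0L))
    return("every item needs at least one non-missing score")
  if (is.null(rownames(sc)) || is.null(colnames(sc)))
    return("scores must carry person ids (rownames) and item ids (colnames)")
  if (anyDuplicated(rownames(sc)))
    return("duplicated person ids")
  if (anyDuplicated(colnames(sc)))
    return("duplicated item ids")
  if (nrow(object@meta) != nrow(sc))
    return("meta must have one row per person")
  if (!all(c("person_id", "timepoint") %in% names(object@meta)))
    return("meta needs columns person_id and timepoint")
  TRUE
})

#' Rating scale model parameters
#'
#' Fitted (or assumed) parameters of the Andrich rating scale model: one
#' difficulty per item on the logit scale and a single set of category
#' thresholds shared by all items.  The model is identified by centering the
#' item difficulties at zero and the thresholds to sum to zero; the person
#' scale is left free.
#'
#' @slot deltas named numeric, item difficulty in logits (mean 0).
#' @slot taus numeric of length \code{nCategories - 1}, category thresholds in
#'   logits (sum 0); the implicit threshold for category 0 is 0.
#' @slot nCategories integer, number of ordered categories.
#' @slot fit list of estimation metadata: \code{iterations}, \code{maxUpdate}
#'   (largest final parameter update in logits), \code{converged}.
#'
#' @seealso [RSMParams()], [fitRSM()], [categoryProbs()]
#' @export
setClass("RSMParams",
         slots = c(deltas = "numeric", taus = "numeric",
                   nCategories = "integer", fit = "list"))

setValidity("RSMParams", function(object) {
  m <- object@nCategories - 1L
  if (length(object@taus) != m)
    return(sprintf("need %d thresholds for %d categories", m,
                   object@nCategories))
  if (!all(is.finite(object@deltas)) || !all(is.finite(object@taus)))
    return("parameters must be finite")
  if (length(object@deltas) < 2L)
    return("need at least 2 items")
  if (abs(mean(object@deltas)) > 1e-6)
    return("item difficulties must be centered at 0 (within 1e-6)")
  if (abs(sum(object@taus)) > 1e-6)
    return("thresholds must sum to 0 (within 1e-6)")
  TRUE
})

#' Fitted rating scale model
#'
#' Result of [fitRSM()]: the estimated measurement model plus one measure per
#' person (row of the input matrix), including finite extrapolated measures
#' for persons with extreme (zero or perfect) raw scores.
#'
#' @slot params an [RSMParams-class] object.
#' @slot persons data.frame of person statistics: \code{person_id},
#'   \code{timepoint}, \code{raw_score}, \code{max_score}, \code{measure}
#'   (logits), \code{se} (logits), \code{extreme} (logical).
#' @slot data the [ResponseMatrix-class] the model was fitted to.
#' @export
setClass("RSMFit",
         slots = c(params = "RSMParams", persons = "data.frame",
                   data = "ResponseMatrix"))

#' Responsiveness index panel
#'
#' The full distribution-based responsiveness panel for one scale version,
#' computed from paired baseline/follow-up person measures on the logit
#' scale: pooled SD, SEM, MDC95, distribution-based MCIDs, effect size with a
#' normal-approximation CI, and the standardized response mean.
#'
#' @slot n integer, number of complete pairs.
#' @slot meanBl,sdBl,meanFu,sdFu numeric, timepoint means and SDs (logits).
#' @slot sdPooled numeric, equal-n pooled SD (logits).
#' @slot reliability numeric in [0, 1), person separation reliability r.
#' @slot sem numeric, standard error of measurement
#'   \eqn{SD_{pooled}\sqrt{1-r}} (logits).
#' @slot mdc95 numeric, minimal detectable change \eqn{1.96\sqrt{2}\,SEM}
#'   (logits).
#' @slot effectSize,esLower,esUpper numeric, mean change over pooled SD and
#'   its approximate 95% CI (unitless).
#' @slot srm numeric, standardized response mean (NA when the panel was built
#'   from summary statistics without person-level changes).
#' @slot meanChange numeric, follow-up minus baseline mean (logits).
#' @slot mcid020,mcid033,mcid050 numeric, distribution-based MCIDs (logits).
#' @export
setClass("ResponsivenessIndices",
         slots = c(n = "integer", meanBl = "numeric", sdBl = "numeric",
                   meanFu = "numeric", sdFu = "numeric", sdPooled = "numeric",
                   reliability = "numeric", sem = "numeric", mdc95 = "numeric",
                   effectSize = "numeric", esLower = "numeric",
                   esUpper = "numeric", srm = "numeric",
                   meanChange = "numeric", mcid020 = "numeric",
                   mcid033 = "numeric", mcid050 = "numeric"))

setValidity("ResponsivenessIndices", function(object) {
  if (object@sdPooled <= 0) return("sdPooled must be > 0")
  if (object@reliability < 0 || object@reliability >= 1)
    return("reliability must lie in [0, 1)")
  if (abs(object@sem - object@sdPooled * sqrt(1 - object@reliability)) > 1e-8)
    return("sem inconsistent with sdPooled and reliability")
  if (abs(object@mdc95 - 1.96 * sqrt(2) * object@sem) > 1e-8)
    return("mdc95 must equal 1.96 * sqrt(2) * sem")
  for (k in c(0.20, 0.33, 0.50)) {
    slot <- sprintf("mcid%03d", round(k * 100))
    if (abs(methods::slot(object, slot) - k * object@sdPooled) > 1e-8)
      return(sprintf("%s must equal %.2f * sdPooled", slot, k))
  }
  if (!(object@mcid020 < object@mcid033 && object@mcid033 < object@mcid050))
    return("MCIDs must be strictly increasing in the SD fraction")
  TRUE
})
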
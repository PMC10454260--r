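#' Pooled standard deviation of two timepoints
#'
#' Equal-n pooled SD for a cohort measured twice:
#' \eqn{\sqrt{(SD_{bl}^2 + SD_{fu}^2)/2}}.
#'
#' @param sdBl,sdFu baseline and follow-up SDs of person measures (logits).
#' @return pooled SD in logits.
#' @examples
#' pooledSD(1.4, 1.1)
#' @export
pooledSD <- function(sdBl, sdFu) {
  if (!is.numeric(sdBl) || !is.numeric(sdFu) || any(sdBl <= 0) ||
      any(sdFu <= 0) || anyNA(sdBl) || anyNA(sdFu))
    .stopCNC("cnc_invalid_argument", "standard deviations must be > 0")
  sqrt((sdBl^2 + sdFu^2) / 2)
}

#' Standard error of measurement
#'
#' \eqn{SEM = SD_{pooled}\sqrt{1 - r}}, with \eqn{r} the person separation
#' reliability.
#'
#' @param sdPooled pooled SD in logits.
#' @param r reliability in \code{[0, 1)}.
#' @return SEM in logits.
#' @examples
#' semMeasurement(1.25, 0.87)  # ~0.45
#' @export
semMeasurement <- function(sdPooled, r) {
  if (!is.numeric(sdPooled) || any(sdPooled <= 0) || anyNA(sdPooled))
    .stopCNC("cnc_invalid_argument", "sdPooled must be > 0")
  if (!is.numeric(r) || anyNA(r) || any(r < 0) || any(r >= 1))
    .stopCNC("cnc_invalid_argument", "reliability must lie in [0, 1)")
  sdPooled * sqrt(1 - r)
}

#' Minimal detectable change at 95% confidence
#'
#' \eqn{MDC_{95} = 1.96\sqrt{2}\,SEM}: the smallest individual change that
#' exceeds measurement error of a test-retest difference at 95% confidence.
#'
#' @param sem standard error of measurement (logits), >= 0.
#' @return MDC95 in logits.
#' @examples
#' mdc95(0.45)  # ~1.25
#' @export
mdc95 <- function(sem) {
  if (!is.numeric(sem) || anyNA(sem) || any(sem < 0))
    .stopCNC("cnc_invalid_argument", "sem must be >= 0")
  1.96 * sqrt(2) * sem
}

#' Distribution-based minimal clinically important difference
#'
#' A fraction of the pooled SD: 0.20 (small), 0.33 (minimally important) or
#' 0.50 (medium) SD units are the conventional group-level benchmarks.
#'
#' @param sdPooled pooled SD in logits.
#' @param k SD fraction in (0, 1).
#' @return MCID in logits (unrounded; see [roundHalfUp()] for reporting).
#' @examples
#' distributionMCID(1.25, 0.33)
#' @export
distributionMCID <- function(sdPooled, k) {
  if (!is.numeric(sdPooled) || any(sdPooled <= 0) || anyNA(sdPooled))
    .stopCNC("cnc_invalid_argument", "sdPooled must be > 0")
  if (!is.numeric(k) || anyNA(k) || any(k <= 0) || any(k >= 1))
    .stopCNC("cnc_invalid_argument", "SD fraction k must lie in (0, 1)")
  k * sdPooled
}

#' Effect size of group change
#'
#' Mean change divided by the pooled SD (unitless).
#'
#' @param meanBl,meanFu baseline and follow-up mean measures (logits).
#' @param sdPooled pooled SD (logits).
#' @return effect size (positive = improvement on the rescored scale).
#' @export
effectSize <- function(meanBl, meanFu, sdPooled) {
  if (!is.numeric(sdPooled) || any(sdPooled <= 0) || anyNA(sdPooled))
    .stopCNC("cnc_invalid_argument", "sdPooled must be > 0")
  (meanFu - meanBl) / sdPooled
}

#' Approximate 95% CI for a paired effect size
#'
#' Normal approximation for a standardized mean difference from paired data:
#' \code{es +- 1.96 * sqrt(1/n + es^2/(2n))}.
#'
#' @param es effect size.
#' @param n number of pairs (>= 2).
#' @return named numeric \code{c(lower, upper)}.
#' @export
effectSizeCI <- function(es, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    .stopCNC("cnc_invalid_argument", "n must be >= 2")
  half <- 1.96 * sqrt(1 / n + es^2 / (2 * n))
  c(lower = es - half, upper = es + half)
}

#' Standardized response mean
#'
#' Mean of per-person change scores divided by their sample SD.
#'
#' @param changes numeric vector of follow-up minus baseline measures
#'   (logits), length >= 2.
#' @return SRM (unitless).
#' @export
standardizedResponseMean <- function(changes) {
  if (!is.numeric(changes) || length(changes) < 2L || anyNA(changes))
    .stopCNC("cnc_invalid_argument", "need >= 2 complete change scores")
  s <- stats::sd(changes)
  if (s == 0)
    .stopCNC("cnc_zero_variance", "change scores have zero variance")
  mean(changes) / s
}

#' Classify an individual change against measurement error
#'
#' A change is \code{"improved"} if it exceeds +MDC95, \code{"declined"} if
#' below -MDC95, and \code{"within_error"} otherwise; a change exactly at the
#' boundary is conservatively read as within error.
#'
#' @param change change score(s) in logits (follow-up minus baseline).
#' @param mdc MDC95 in logits, > 0.
#' @return factor with levels \code{declined}, \code{within_error},
#'   \code{improved}.
#' @examples
#' classifyChange(c(1.3, -1.3, 0.1, 1.25), mdc = 1.25)
#' @export
classifyChange <- function(change, mdc) {
  if (!is.numeric(mdc) || length(mdc) != 1L || is.na(mdc) || mdc <= 0)
    .stopCNC("cnc_invalid_argument", "mdc must be a single value > 0")
  out <- ifelse(change > mdc, "improved",
                ifelse(change < -mdc, "declined", "within_error"))
  factor(out, levels = c("declined", "within_error", "improved"))
}

#' Pair baseline and follow-up measures by person
#'
#' Matches person measures across two timepoints into complete pairs, as
#' needed by [computeIndices()] and [summarizeChange()].
#'
#' @param measures an [RSMFit-class] from a stacked calibration, or its
#'   [personMeasures()] data.frame carrying \code{person_id},
#'   \code{timepoint} and \code{measure} columns.
#' @param baseline,followup timepoint labels.
#' @return data.frame with columns \code{person_id}, \code{baseline},
#'   \code{followup}, \code{change} (logits); persons missing either
#'   timepoint are dropped.
#' @export
pairMeasures <- function(measures, baseline = "baseline",
                         followup = "followup") {
  if (methods::is(measures, "RSMFit")) measures <- personMeasures(measures)
  bl <- measures[measures$timepoint == baseline, ]
  fu <- measures[measures$timepoint == followup, ]
  ids <- intersect(bl$person_id, fu$person_id)
  if (length(ids) < 2L)
    .stopCNC("cnc_invalid_argument",
             "need >= 2 persons with both timepoints (found %d)", length(ids))
  b <- bl$measure[match(ids, bl$person_id)]
  f <- fu$measure[match(ids, fu$person_id)]
  data.frame(person_id = ids, baseline = b, followup = f, change = f - b,
             stringsAsFactors = FALSE)
}

#' Tabulate beyond-error change in a cohort
#'
#' Counts and proportions of persons classified by [classifyChange()], plus
#' the improved/declined split among those whose change exceeds measurement
#' error.
#'
#' @param paired data.frame from [pairMeasures()] (or with a \code{change}
#'   column).
#' @param mdc MDC95 in logits.
#' @return list with \code{counts}, \code{proportions} (both named by
#'   category), \code{n}, \code{beyond_error} (count), and
#'   \code{beyond_error_split} (improved/declined counts and shares among
#'   beyond-error changers).
#' @export
summarizeChange <- function(paired, mdc) {
  change <- if (is.data.frame(paired)) paired$change else paired
  cl <- classifyChange(change, mdc)
  counts <- table(cl)
  n <- length(change)
  beyond <- sum(counts[c("improved", "declined")])
  split <- c(improved = unname(counts["improved"]),
             declined = unname(counts["declined"]))
  list(counts = c(counts), proportions = c(counts) / n, n = n,
       beyond_error = unname(beyond),
       beyond_error_split = list(
         counts = split,
         proportions = if (beyond > 0) split / beyond else split * NA_real_))
}

#' Ability band around a measure
#'
#' The one-SEM uncertainty band \code{measure +- sem}, the range a clinician
#' reads as the patient's plausible ability.
#'
#' @param measure person measure in logits.
#' @param sem standard error of measurement in logits, > 0.
#' @return named numeric \code{c(lower, upper)}.
#' @examples
#' measureBand(-1.86, 0.45)  # -2.31 to -1.41
#' @export
measureBand <- function(measure, sem) {
  if (!is.numeric(sem) || any(sem <= 0) || anyNA(sem))
    .stopCNC("cnc_invalid_argument", "sem must be > 0")
  c(lower = measure - sem, upper = measure + sem)
}

#' Threshold for true individual change
#'
#' The measure a patient must reach before their change from \code{measure}
#' counts as beyond measurement error: \code{measure + mdc} for improvement,
#' \code{measure - mdc} for decline.
#'
#' @param measure starting measure in logits.
#' @param mdc MDC95 in logits, > 0.
#' @param direction \code{"improvement"} or \code{"decline"}.
#' @return threshold measure in logits.
#' @examples
#' trueChangeThreshold(-1.86, 1.25)  # -0.61
#' @export
trueChangeThreshold <- function(measure, mdc,
                                direction = c("improvement", "decline")) {
  if (!is.numeric(mdc) || any(mdc <= 0) || anyNA(mdc))
    .stopCNC("cnc_invalid_argument", "mdc must be > 0")
  direction <- match.arg(direction)
  if (direction == "improvement") measure + mdc else measure - mdc
}

.newIndices <- function(n, meanBl, sdBl, meanFu, sdFu, sdPooled, r, srm) {
  sem <- semMeasurement(sdPooled, r)
  es <- effectSize(meanBl, meanFu, sdPooled)
  ci <- effectSizeCI(es, n)
  methods::new("ResponsivenessIndices",
               n = as.integer(n), meanBl = meanBl, sdBl = sdBl,
               meanFu = meanFu, sdFu = sdFu, sdPooled = sdPooled,
               reliability = r, sem = sem, mdc95 = mdc95(sem),
               effectSize = es, esLower = unname(ci["lower"]),
               esUpper = unname(ci["upper"]), srm = srm,
               meanChange = meanFu - meanBl,
               mcid020 = distributionMCID(sdPooled, 0.20),
               mcid033 = distributionMCID(sdPooled, 0.33),
               mcid050 = distributionMCID(sdPooled, 0.50))
}

#' Compute the full responsiveness panel from paired measures
#'
#' Assembles the distribution-based responsiveness indices — pooled SD, SEM,
#' MDC95, MCIDs at 0.20/0.33/0.50 SD, effect size with approximate CI, and
#' SRM — from complete baseline/follow-up pairs and an externally supplied
#' person separation reliability (see [wrightPSR()]).
#'
#' @param paired data.frame from [pairMeasures()].
#' @param r person separation reliability in \code{[0, 1)}.
#' @param sdPooled optional override of the pooled SD (logits); when given,
#'   published summary values can be used in place of the recomputed one.
#' @return a [ResponsivenessIndices-class] object.
#' @seealso [responsivenessFromSummary()] for panel construction from
#'   published summary statistics alone.
#' @export
computeIndices <- function(paired, r, sdPooled = NULL) {
  if (!is.data.frame(paired) || nrow(paired) < 2L)
    .stopCNC("cnc_invalid_argument", "need >= 2 complete pairs")
  if (anyNA(paired$baseline) || anyNA(paired$followup))
    .stopCNC("cnc_invalid_argument", "pairs must be complete")
  sdBl <- stats::sd(paired$baseline)
  sdFu <- stats::sd(paired$followup)
  sdp <- sdPooled %||% pooledSD(sdBl, sdFu)
  changes <- paired$followup - paired$baseline
  srm <- if (stats::sd(changes) > 0) standardizedResponseMean(changes)
         else NA_real_
  .newIndices(nrow(paired), mean(paired$baseline), sdBl,
              mean(paired$followup), sdFu, sdp, r, srm)
}

#' Responsiveness panel from summary statistics
#'
#' Builds the index panel from published timepoint summaries (means, SDs or
#' a pooled SD, reliability) without person-level data, e.g. to reproduce a
#' published table.
#'
#' @param n number of persons.
#' @param meanBl,meanFu timepoint means (logits).
#' @param sdBl,sdFu timepoint SDs (logits); optional if \code{sdPooled} given.
#' @param r person separation reliability in \code{[0, 1)}.
#' @param sdPooled optional pooled SD (logits) overriding
#'   \code{pooledSD(sdBl, sdFu)}.
#' @return a [ResponsivenessIndices-class] (SRM is \code{NA}: it needs
#'   person-level change scores).
#' @export
responsivenessFromSummary <- function(n, meanBl, meanFu, sdBl = NA_real_,
                                      sdFu = NA_real_, r, sdPooled = NULL) {
  sdp <- sdPooled %||% pooledSD(sdBl, sdFu)
  .newIndices(n, meanBl, sdBl, meanFu, sdFu, sdp, r, NA_real_)
}

#' Report the index panel with published-style rounding
#'
#' @param x a [ResponsivenessIndices-class].
#' @param digits decimal places (default 2, rounded half away from zero).
#' @return one-row data.frame with the panel's headline columns, named after
#'   the conventional report headers.
#' @export
reportIndices <- function(x, digits = 2L) {
  stopifnot(methods::is(x, "ResponsivenessIndices"))
  r2 <- function(v) roundHalfUp(v, digits)
  data.frame(
    n = x@n,
    `SD_pooled` = r2(x@sdPooled),
    `Person Separation Reliability` = r2(x@reliability),
    `Standard error of measurement` = r2(x@sem),
    `Effect size` = r2(x@effectSize),
    `Lower 95% CI` = r2(x@esLower),
    `Upper 95% CI` = r2(x@esUpper),
    `Standardized response mean` = r2(x@srm),
    `MDC_95` = r2(x@mdc95),
    `MCID 0.20 SD` = r2(x@mcid020),
    `MCID 0.33 SD` = r2(x@mcid033),
    `MCID 0.50 SD` = r2(x@mcid050),
    check.names = FALSE)
}

setMethod("show", "ResponsivenessIndices", function(object) {
  cat(sprintf("Responsiveness indices (n = %d pairs, logit scale)\n",
              object@n))
  cat(sprintf("  baseline %.2f (SD %.2f)  follow-up %.2f (SD %.2f)\n",
              object@meanBl, object@sdBl, object@meanFu, object@sdFu))
  cat(sprintf("  SD_pooled %.2f   reliability %.2f   SEM %.2f\n",
              object@sdPooled, object@reliability, object@sem))
  cat(sprintf("  MDC_95 %.2f   MCID 0.20/0.33/0.50 SD: %.2f / %.2f / %.2f\n",
              roundHalfUp(object@mdc95), roundHalfUp(object@mcid020),
              roundHalfUp(object@mcid033), roundHalfUp(object@mcid050)))
  cat(sprintf("  effect size %.2f (95%% CI %.2f, %.2f)   SRM %s\n",
              object@effectSize, object@esLower, object@esUpper,
              ifelse(is.na(object@srm), "NA", sprintf("%.2f", object@srm))))
})

#' Export an index panel as JSON
#'
#' @param x a [ResponsivenessIndices-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeIndicesJSON <- function(x, path) {
  stopifnot(methods::is(x, "ResponsivenessIndices"))
  vals <- list(n = x@n, mean_baseline = x@meanBl, sd_baseline = x@sdBl,
               mean_followup = x@meanFu, sd_followup = x@sdFu,
               sd_pooled = x@sdPooled, reliability = x@reliability,
               sem = x@sem, mdc95 = x@mdc95, effect_size = x@effectSize,
               effect_size_ci = c(x@esLower, x@esUpper), srm = x@srm,
               mean_change = x@meanChange, mcid_020 = x@mcid020,
               mcid_033 = x@mcid033, mcid_050 = x@mcid050)
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
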
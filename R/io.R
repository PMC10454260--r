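#' Read an assessment CSV into response matrices
#'
#' Expects a UTF-8 comma-separated file with header
#' \code{person_id, timepoint, item_1..item_L}; empty cells are missing
#' responses.  Values are either original CNC codes \code{0/2/4}
#' (\code{scoring = "original"}, rescored on read so that higher = better)
#' or already-rescored \code{0/1/2}.
#'
#' @param path file path.
#' @param scoring coding convention of the file.
#' @param timepoints ordered pair of admissible timepoint labels.
#' @param nCategories categories after rescoring (default 3).
#' @return named list of [ResponseMatrix-class], one per timepoint present,
#'   in \code{timepoints} order.
#' @export
readAssessments <- function(path, scoring = c("rescored", "original"),
                            timepoints = c("baseline", "followup"),
                            nCategories = 3L) {
  scoring <- match.arg(scoring)
  if (!file.exists(path))
    .stopCNC("cnc_invalid_argument", "file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", na.strings = "")
  need <- c("person_id", "timepoint")
  if (!all(need %in% names(df)) || ncol(df) < 4L)
    .stopCNC("cnc_malformed_file",
             "%s: header must be person_id, timepoint, item_1..item_L", path)
  itemCols <- setdiff(names(df), need)
  dup <- duplicated(df[need])
  if (any(dup)) {
    i <- which(dup)[1L]
    .stopCNC("cnc_duplicate_record",
             "%s line %d: duplicate record for person '%s' timepoint '%s'",
             path, i + 1L, df$person_id[i], df$timepoint[i])
  }
  badTp <- !(df$timepoint %in% timepoints)
  if (any(badTp))
    .stopCNC("cnc_malformed_file",
             "%s line %d: unknown timepoint '%s' (expected %s)",
             path, which(badTp)[1L] + 1L, df$timepoint[which(badTp)[1L]],
             paste(timepoints, collapse = "/"))
  vals <- suppressWarnings(
    vapply(df[itemCols], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, itemCols))
  allowed <- if (scoring == "original") c(0, 2, 4)
             else 0:(nCategories - 1L)
  bad <- which(!is.na(vals) & !(vals %in% allowed), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    .stopCNC("cnc_invalid_value",
             "%s line %d, column %s: invalid code '%s' for %s scoring",
             path, bad[1L, 1L] + 1L, itemCols[bad[1L, 2L]],
             df[[itemCols[bad[1L, 2L]]]][bad[1L, 1L]], scoring)
  if (scoring == "original") vals <- rescoreCNC(vals)
  out <- list()
  for (tp in timepoints) {
    rows <- df$timepoint == tp
    if (!any(rows)) next
    out[[tp]] <- ResponseMatrix(vals[rows, , drop = FALSE],
                                personIds = df$person_id[rows],
                                itemIds = itemCols,
                                nCategories = nCategories, timepoint = tp)
  }
  out
}

#' Write a cohort to the assessment CSV format
#'
#' Inverse of [readAssessments()]: one row per person-timepoint, rescored
#' \code{0/1/2} codes, empty cells for missing responses.
#'
#' @param cohort a named list of [ResponseMatrix-class] objects (e.g. the
#'   \code{baseline}/\code{followup} elements of [simulateCohort()] output),
#'   or a single matrix.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAssessments <- function(cohort, path) {
  if (methods::is(cohort, "ResponseMatrix")) cohort <- list(cohort)
  rows <- lapply(cohort, function(rm) {
    sc <- scores(rm)
    data.frame(person_id = rm@meta$person_id,
               timepoint = rm@meta$timepoint,
               as.data.frame(sc, row.names = NULL),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Published CNC score-to-measure conversion table
#'
#' The published conversion between original-scale CNC total raw scores
#' (0/2/4 coding, lower = better function) and logit person measures for the
#' 8-item and 10-item versions, packaged as a reference fixture.  Totals
#' 34-40 exist only for the 10-item version.
#'
#' @return data.frame with columns \code{original_total},
#'   \code{measure_8item}, \code{measure_10item}.
#' @export
cncConversionFixture <- function() {
  utils::read.csv(system.file("extdata", "cnc_conversion_published.csv",
                              package = "cncrasch"))
}

#' Published CNC responsiveness summaries
#'
#' Timepoint means/SDs, pooled SD, person separation reliability and the
#' derived indices published for the 8-item (no pain items) and 10-item
#' CNC versions, packaged as reference fixtures.
#'
#' @return data.frame, one row per scale version.
#' @export
cncIndicesFixture <- function() {
  utils::read.csv(system.file("extdata", "cnc_responsiveness_published.csv",
                              package = "cncrasch"), check.names = FALSE)
}

#' @rdname cncIndicesFixture
#' @export
cncMDCFixture <- function() {
  utils::read.csv(system.file("extdata", "cnc_mdc_mcid_published.csv",
                              package = "cncrasch"), check.names = FALSE)
}

#' Look up a published person measure for a raw total
#'
#' @param originalTotal CNC total on the original 0/2/4 coding.
#' @param version scale version, 8 or 10 items.
#' @param table conversion table (defaults to the packaged published one).
#' @return measure in logits.
#' @examples
#' lookupMeasure(28, version = 8)   # -1.86
#' @export
lookupMeasure <- function(originalTotal, version = c(8, 10),
                          table = cncConversionFixture()) {
  version <- match.arg(as.character(version[1L]), c("8", "10"))
  col <- paste0("measure_", version, "item")
  i <- match(originalTotal, table$original_total)
  bad <- is.na(i) | is.na(table[[col]][ifelse(is.na(i), 1L, i)])
  if (any(bad)) {
    valid <- table$original_total[!is.na(table[[col]])]
    .stopCNC("cnc_invalid_argument",
             "total %s not in the %s-item table (valid totals: %s)",
             format(originalTotal[bad][1L]), version,
             paste(range(valid), collapse = "-"))
  }
  table[[col]][i]
}

#' Write fitted model parameters as JSON
#'
#' @param params an [RSMParams-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeParamsJSON <- function(params, path) {
  stopifnot(methods::is(params, "RSMParams"))
  jsonlite::write_json(
    list(deltas = as.list(itemDifficulties(params)),
         taus = thresholds(params),
         n_categories = nCategories(params),
         fit = params@fit),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeParamsJSON
#' @return for \code{readParamsJSON}, the reconstructed [RSMParams-class].
#' @export
readParamsJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  RSMParams(deltas = unlist(x$deltas), taus = x$taus,
            fit = as.list(x$fit))
}
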
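#' Build a ResponseMatrix
#'
#' @param scores numeric/integer matrix of category scores (persons in rows,
#'   items in columns), values in \code{0..(nCategories-1)} or \code{NA}.
#' @param personIds,itemIds optional identifier vectors; default to existing
#'   dimnames or \code{P1..Pn} / \code{item_1..item_L}.
#' @param nCategories number of ordered categories (CNC rescored 0/1/2: 3).
#' @param timepoint optional single label or per-person vector stored in the
#'   metadata (e.g. \code{"baseline"}).
#' @return a validated [ResponseMatrix-class] object.
#' @examples
#' m <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 2, byrow = TRUE)
#' ResponseMatrix(m, personIds = c("P1", "P2"))
#' @export
ResponseMatrix <- function(scores, personIds = NULL, itemIds = NULL,
                           nCategories = 3L, timepoint = NA_character_) {
  scores <- as.matrix(scores)
  if (is.null(personIds))
    personIds <- rownames(scores) %||% paste0("P", seq_len(nrow(scores)))
  if (is.null(itemIds))
    itemIds <- colnames(scores) %||% paste0("item_", seq_len(ncol(scores)))
  storage.mode(scores) <- "integer"
  dimnames(scores) <- list(as.character(personIds), as.character(itemIds))
  meta <- data.frame(person_id = as.character(personIds),
                     timepoint = rep_len(as.character(timepoint), nrow(scores)),
                     stringsAsFactors = FALSE)
  methods::new("ResponseMatrix", scores = scores,
               nCategories = as.integer(nCategories), meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an RSMParams object
#'
#' @param deltas numeric item difficulties (logits); centered to mean 0 on
#'   construction if not already.
#' @param taus numeric category thresholds (logits); centered to sum 0.
#' @param fit optional list of estimation metadata.
#' @return a validated [RSMParams-class] object.
#' @examples
#' RSMParams(deltas = c(-0.5, 0, 0.5), taus = c(-1, 1))
#' @export
RSMParams <- function(deltas, taus, fit = list()) {
  if (!all(is.finite(deltas)) || !all(is.finite(taus)))
    .stopCNC("cnc_invalid_argument", "deltas and taus must be finite")
  deltas <- deltas - mean(deltas)
  taus <- taus - mean(taus)
  if (is.null(names(deltas))) names(deltas) <- paste0("item_", seq_along(deltas))
  methods::new("RSMParams", deltas = deltas, taus = as.numeric(taus),
               nCategories = length(taus) + 1L, fit = fit)
}

#' Stack two timepoints into one calibration matrix
#'
#' Concatenates the baseline and follow-up response matrices row-wise so that
#' a single set of item and threshold parameters is estimated from both
#' assessments (stacked calibration); person metadata keeps track of which
#' row belongs to which person-timepoint.
#'
#' @param baseline,followup [ResponseMatrix-class] objects with identical
#'   items and categories.
#' @param labels length-2 character, timepoint labels in order.
#' @return a stacked [ResponseMatrix-class].
#' @export
stackTimepoints <- function(baseline, followup,
                            labels = c("baseline", "followup")) {
  if (!identical(itemIds(baseline), itemIds(followup)))
    .stopCNC("cnc_invalid_argument", "timepoints must share the same items")
  if (nCategories(baseline) != nCategories(followup))
    .stopCNC("cnc_invalid_argument", "timepoints must share nCategories")
  sc <- rbind(scores(baseline), scores(followup))
  ids <- c(personIds(baseline), personIds(followup))
  tp <- rep(labels, c(nrow(scores(baseline)), nrow(scores(followup))))
  rownames(sc) <- paste(ids, tp, sep = "@")
  out <- ResponseMatrix(sc, nCategories = nCategories(baseline))
  out@meta$person_id <- ids
  out@meta$timepoint <- tp
  out
}

#' @rdname ResponseMatrix-class
#' @export
setMethod("scores", "ResponseMatrix", function(x) x@scores)

#' @rdname ResponseMatrix-class
#' @export
setMethod("personIds", "ResponseMatrix", function(x) x@meta$person_id)

#' @rdname ResponseMatrix-class
#' @export
setMethod("itemIds", "ResponseMatrix", function(x) colnames(x@scores))

#' @rdname ResponseMatrix-class
#' @export
setMethod("nCategories", "ResponseMatrix", function(x) x@nCategories)

#' @rdname ResponseMatrix-class
#' @export
setMethod("dim", "ResponseMatrix", function(x) dim(x@scores))

setMethod("show", "ResponseMatrix", function(object) {
  sc <- object@scores
  cat(sprintf("ResponseMatrix: %d persons x %d items, %d categories\n",
              nrow(sc), ncol(sc), object@nCategories))
  miss <- mean(is.na(sc))
  cat(sprintf("  missing: %.1f%%; timepoints: %s\n", 100 * miss,
              paste(unique(object@meta$timepoint), collapse = ", ")))
})

#' @rdname RSMParams-class
#' @export
setMethod("itemDifficulties", "RSMParams", function(x) x@deltas)

#' @rdname RSMParams-class
#' @export
setMethod("thresholds", "RSMParams", function(x) x@taus)

#' @rdname RSMParams-class
#' @export
setMethod("nCategories", "RSMParams", function(x) x@nCategories)

setMethod("show", "RSMParams", function(object) {
  cat(sprintf("RSMParams: %d items, %d categories\n",
              length(object@deltas), object@nCategories))
  cat("  item difficulties (logits):\n")
  print(round(object@deltas, 3))
  cat("  thresholds (logits):", paste(round(object@taus, 3), collapse = ", "),
      "\n")
  if (length(object@fit))
    cat(sprintf("  fit: %d iterations, max update %.2e, converged: %s\n",
                object@fit$iterations, object@fit$maxUpdate,
                object@fit$converged))
})

#' @rdname RSMFit-class
#' @export
setMethod("modelParams", "RSMFit", function(x) x@params)

#' @rdname RSMFit-class
#' @export
setMethod("personMeasures", "RSMFit", function(x) x@persons)

#' @rdname RSMFit-class
#' @export
setMethod("itemDifficulties", "RSMFit", function(x) x@params@deltas)

#' @rdname RSMFit-class
#' @export
setMethod("thresholds", "RSMFit", function(x) x@params@taus)

setMethod("show", "RSMFit", function(object) {
  cat("Rating scale model fit (JMLE)\n")
  show(object@params)
  p <- object@persons
  cat(sprintf("  %d person measures (%d extreme), range %.2f to %.2f logits\n",
              nrow(p), sum(p$extreme), min(p$measure), max(p$measure)))
})
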
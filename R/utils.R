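# internal helpers shared across the package

# structured conditions so callers can branch on failure type
.stopCNC <- function(class, fmt, ...) {
  stop(structure(class = c(class, "cnc_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1L))))
}

.assertFiniteScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x)))
    .stopCNC("cnc_invalid_argument", "'%s' must be finite numeric", name)
  invisible(x)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round half away from zero
#'
#' Reporting convention for the index panel: conventional rounding with ties
#' going away from zero (so 0.625 reports as 0.63), unlike base R's
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' roundHalfUp(0.625, 2)  # 0.63
#' @export
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
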
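# shared internal helpers

#' Round half away from zero
#'
#' Reporting convention used throughout the package: somatotype components and
#' group statistics are printed to a fixed number of decimals with halves
#' rounded away from zero (so 1.95 -> 2.0, -1.95 -> -2.0), unlike base
#' [round()] which rounds halves to even. Internal computation is always full
#' precision; this is applied only when formatting results.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(1.25, 1.35, -1.25), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  out <- sign(x) * floor(abs(x) * p + 0.5) / p
  # reporting helper: carry names only, drop provenance attributes
  attributes(out) <- NULL
  names(out) <- names(x)
  out
}

# stop with a field-named message when a value is not positive finite
check_positive <- function(x, field) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    stop(sprintf("'%s' must be positive and finite (got %s)",
                 field, format(x[which(bad)[1]])), call. = FALSE)
  }
  invisible(x)
}

# nonnegative finite check (zero allowed)
check_nonneg <- function(x, field) {
  bad <- !is.finite(x) | x < 0
  if (any(bad)) {
    stop(sprintf("'%s' must be nonnegative and finite (got %s)",
                 field, format(x[which(bad)[1]])), call. = FALSE)
  }
  invisible(x)
}

# require named columns in a cohort data frame
check_columns <- function(data, cols, where) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 where, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(data)
}
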
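# Cross-validation agreement statistics: pure error, Lin's concordance
# correlation coefficient with its precision/accuracy decomposition, and
# Bland-Altman limits of agreement.
#
# Sign convention, stated in every report: differences are always
# predicted - reference, so a negative bias means the prediction runs below
# the reference method.

#' Pure error of a prediction on held-out data
#'
#' `sqrt( sum((predicted - observed)^2) / n )`: the root mean squared
#' difference between predicted and observed values, in response units. Unlike
#' the SEE it charges bias as well as scatter.
#'
#' @param predicted,observed equal-length numeric vectors, n >= 1.
#' @return pure error (scalar, >= 0).
#' @export
#' @examples
#' pure_error(c(2.1, 2.9), c(2.0, 3.0))  # 0.1
pure_error <- function(predicted, observed) {
  if (!length(predicted) || length(predicted) != length(observed)) {
    stop("pure_error: 'predicted' and 'observed' must be equal-length, n >= 1",
         call. = FALSE)
  }
  sqrt(sum((predicted - observed)^2) / length(predicted))
}

#' Lin's concordance correlation coefficient
#'
#' Concordance between two measurements of the same quantity:
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`,
#' with population (n-denominator) moments in the original Lin formulation
#' (the n-1 variant is available via `denominator`). The decomposition
#' `CCC = rho * C_b` splits concordance into precision (Pearson correlation
#' `rho`, scatter about the best-fit line) and accuracy (`C_b`, how far the
#' best-fit line sits from the 45-degree identity line); the identity holds to
#' machine precision by construction.
#'
#' @param x,y numeric vectors, n >= 3, each with nonzero variance.
#' @param denominator `"n"` (Lin's original, default) or `"n-1"`.
#' @return list: `ccc`, `rho` (precision), `c_b` (accuracy).
#' @export
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))  # ccc = 4/7, rho = 1
lin_ccc <- function(x, y, denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  n <- length(x)
  if (n < 3 || length(y) != n) {
    stop("lin_ccc: need equal-length vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("lin_ccc: undefined for zero-variance input", call. = FALSE)
  }
  f <- if (denominator == "n") (n - 1) / n else 1
  vx <- stats::var(x) * f
  vy <- stats::var(y) * f
  cxy <- stats::cov(x, y) * f
  ccc <- 2 * cxy / (vx + vy + (mean(x) - mean(y))^2)
  rho <- stats::cor(x, y)
  list(ccc = ccc, rho = rho, c_b = ccc / rho)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = predicted - reference`; bias is `mean(d)`, the 95% limits
#' of agreement are `bias +/- z * SD(d)` (sample SD, n-1 denominator,
#' z = 1.96 by default), and the trend is the Pearson correlation of the
#' differences with the pair means together with its two-sided p-value. With
#' zero-variance differences (e.g. identical vectors) the trend is reported
#' as not applicable (`NA`).
#'
#' @param predicted,reference numeric vectors, n >= 3.
#' @param z limits-of-agreement multiplier (default 1.96).
#' @return list: `bias`, `sd_diff`, `loa_low`, `loa_high`, `trend_r`,
#'   `trend_p`, `n`.
#' @export
#' @examples
#' bland_altman(c(1.8, 3.0, 4.2), c(2.0, 3.0, 4.0))
bland_altman <- function(predicted, reference, z = 1.96) {
  n <- length(predicted)
  if (n < 3 || length(reference) != n) {
    stop("bland_altman: need equal-length vectors with n >= 3", call. = FALSE)
  }
  d <- predicted - reference
  m <- (predicted + reference) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  if (s == 0 || stats::sd(m) == 0) {
    trend_r <- NA_real_
    trend_p <- NA_real_
  } else {
    ct <- stats::cor.test(d, m)
    trend_r <- unname(ct$estimate)
    trend_p <- ct$p.value
  }
  list(bias = bias, sd_diff = s,
       loa_low = bias - z * s, loa_high = bias + z * s,
       trend_r = trend_r, trend_p = trend_p, n = n)
}

#' Cross-validate somatotype predictions against the Heath-Carter reference
#'
#' Computes the reference somatotype (full Heath-Carter engine) and the
#' predicted somatotype (either the bundled equation registry or three
#' freshly fitted [stepwise_ols()] models) on a validation cohort, then per
#' component: coefficient of determination (squared Pearson correlation of
#' predicted vs reference), pure error, Lin's CCC with its precision/accuracy
#' decomposition, and Bland-Altman bias, limits of agreement and trend.
#'
#' @param validation validation cohort data frame (full anthropometry + BIA).
#' @param models optional named list with elements `endomorphy`, `mesomorphy`,
#'   `ectomorphy`, each a `"prediction_model"`; when `NULL` the bundled
#'   `equations` are used.
#' @param equations equation registry entry used when `models` is `NULL`.
#' @param z limits-of-agreement multiplier.
#' @return object of class `"agreement_report"`: a data frame with one row
#'   per component and columns `component`, `r_squared`, `pure_error`, `ccc`,
#'   `rho`, `c_b`, `bias`, `loa_low`, `loa_high`, `trend_r`, `trend_p`, `n`.
#'   The difference direction (`predicted - reference`) and prediction source
#'   are attached as attributes and printed in the report header.
#' @export
cross_validate <- function(validation, models = NULL,
                           equations = somatotype_equations(), z = 1.96) {
  ref <- somatotype_reference(validation)
  if (is.null(models)) {
    pred <- predict_somatotype(validation, equations)
    source <- paste0("equation registry '", equations$id, "'")
  } else {
    stopifnot(all(c("endomorphy", "mesomorphy", "ectomorphy") %in% names(models)))
    cand <- candidate_set(validation)
    pred <- data.frame(
      endomorphy = pmax(predict(models$endomorphy, cand), SOMATOTYPE_FLOOR),
      mesomorphy = pmax(predict(models$mesomorphy, cand), SOMATOTYPE_FLOOR),
      ectomorphy = pmax(predict(models$ectomorphy, cand), SOMATOTYPE_FLOOR))
    source <- "fitted stepwise models"
  }
  rows <- lapply(c("endomorphy", "mesomorphy", "ectomorphy"), function(comp) {
    p <- pred[[comp]]
    r <- ref[[comp]]
    cc <- lin_ccc(p, r)
    ba <- bland_altman(p, r, z)
    data.frame(component = comp,
               r_squared = stats::cor(p, r)^2,
               pure_error = pure_error(p, r),
               ccc = cc$ccc, rho = cc$rho, c_b = cc$c_b,
               bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
               trend_r = ba$trend_r, trend_p = ba$trend_p, n = ba$n)
  })
  out <- do.call(rbind, rows)
  attr(out, "direction") <- "predicted - reference"
  attr(out, "source") <- source
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Cross-validation of somatotype predictions against the Heath-Carter reference\n")
  cat("  predictions:", attr(x, "source"), "\n")
  cat("  difference direction:", attr(x, "direction"), "\n\n")
  fmt <- data.frame(
    Component = paste0(toupper(substring(x$component, 1, 1)),
                       substring(x$component, 2)),
    `R2` = sprintf("%.2f", x$r_squared),
    PE = sprintf("%.3f", x$pure_error),
    CCC = sprintf("%.2f", x$ccc),
    rho = sprintf("%.4f", x$rho),
    Cb = sprintf("%.4f", x$c_b),
    Bias = sprintf("%.4f", x$bias),
    `LoA` = sprintf("%.3f; %.3f", x$loa_low, x$loa_high),
    Trend = ifelse(is.na(x$trend_r), "n/a",
                   sprintf("r = %.3f (p = %.3f)", x$trend_r, x$trend_p)),
    check.names = FALSE)
  print(fmt, row.names = FALSE)
  invisible(x)
}
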
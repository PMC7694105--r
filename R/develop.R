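# Equation-development machinery: stratified splitting, the candidate
# predictor table, stepwise OLS with partial-F entry/removal, variance
# inflation factors and residual diagnostics.

#' Stratified random split into development and validation groups
#'
#' Assigns athletes to a validation group of size `round(n * fraction)` and a
#' development group with the remainder, stratified so that each stratum's
#' validation count is its exact proportional share rounded by the
#' largest-remainder method (every stratum differs from exact proportionality
#' by less than one athlete). Reproducible under a fixed seed; a stratum with
#' a single member goes to the development group with a warning.
#'
#' @param cohort cohort data frame.
#' @param fraction_validation proportion assigned to validation, in (0, 1).
#' @param strata stratification column name (default `"position"`); `NA`
#'   values form their own stratum.
#' @param seed integer seed (required).
#' @return list with elements `development` and `validation`; union is the
#'   input, intersection empty.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 176, seed = 7))
#' sp <- stratified_split(cohort, 1 / 3, seed = 7)
#' nrow(sp$validation)  # 59
stratified_split <- function(cohort, fraction_validation = 1 / 3,
                             strata = "position", seed) {
  if (missing(seed)) stop("stratified_split: 'seed' is required", call. = FALSE)
  if (!is.numeric(fraction_validation) || fraction_validation <= 0 ||
      fraction_validation >= 1) {
    stop("'fraction_validation' must lie strictly between 0 and 1",
         call. = FALSE)
  }
  check_columns(cohort, strata, "stratified_split")
  n <- nrow(cohort)
  g <- as.character(cohort[[strata]])
  g[is.na(g)] <- "<missing>"
  target_total <- round(n * fraction_validation)
  # largest-remainder allocation of the validation total across strata
  tab <- table(g)
  exact <- as.numeric(tab) * target_total / n
  base <- floor(exact)
  rem <- exact - base
  left <- target_total - sum(base)
  if (left > 0) {
    ord <- order(rem, as.numeric(tab), names(tab),
                 decreasing = c(TRUE, TRUE, FALSE), method = "radix")
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  names(base) <- names(tab)
  singletons <- names(tab)[tab == 1 & base > 0]
  if (length(singletons)) {
    warning(sprintf("stratum(s) with a single member assigned to development: %s",
                    paste(singletons, collapse = ", ")), call. = FALSE)
    base[singletons] <- 0
  }
  set.seed(as.integer(seed))
  val_idx <- integer(0)
  for (s in sort(names(tab))) {
    members <- which(g == s)
    k <- base[[s]]
    if (k > 0) val_idx <- c(val_idx, sort(sample(members, k)))
  }
  val_idx <- sort(val_idx)
  list(development = cohort[setdiff(seq_len(n), val_idx), , drop = FALSE],
       validation = cohort[val_idx, , drop = FALSE])
}

#' Candidate predictor table for equation development
#'
#' Builds the full candidate set used in stepwise development from a cohort
#' table, recomputing every derived column from raw measurements (never
#' ingesting them): age, resistance, reactance, phase angle, fat-free mass,
#' fat mass, fat mass percentage, fat-free mass / stature, stature, weight,
#' BMI, the four skinfolds, the two girths, stature^2/resistance and
#' stature^2/reactance. Skinfolds and girths enter as individual columns.
#'
#' @param cohort cohort data frame.
#' @return data frame of 19 numeric candidate columns, one row per athlete.
#' @export
candidate_set <- function(cohort) {
  comp <- body_composition(cohort)
  data.frame(
    age = cohort$age,
    resistance_ohm = cohort$resistance_ohm,
    reactance_ohm = cohort$reactance_ohm,
    phase_angle = comp$phase_angle,
    ffm_kg = comp$ffm_kg,
    fm_kg = comp$fm_kg,
    fm_percent = comp$fm_percent,
    ffm_stature = comp$ffm_kg / cohort$stature_cm,
    stature_cm = cohort$stature_cm,
    weight_kg = cohort$weight_kg,
    bmi = body_mass_index(cohort$weight_kg, cohort$stature_cm),
    triceps_mm = cohort$triceps_mm,
    subscapular_mm = cohort$subscapular_mm,
    supraspinal_mm = cohort$supraspinal_mm,
    medial_calf_mm = cohort$medial_calf_mm,
    arm_girth_cm = cohort$arm_girth_cm,
    calf_girth_cm = cohort$calf_girth_cm,
    s2_resistance = comp$s2_resistance,
    s2_reactance = comp$s2_reactance)
}

# residual sum of squares and residual df of y ~ X (with intercept)
ols_rss <- function(y, data, predictors) {
  if (!length(predictors)) {
    return(list(rss = sum((y - mean(y))^2), df = length(y) - 1L, fit = NULL))
  }
  fit <- stats::lm(stats::reformulate(predictors, response = ".y"),
                   data = cbind(.y = y, data))
  list(rss = sum(stats::residuals(fit)^2), df = fit$df.residual, fit = fit,
       aliased = names(which(is.na(stats::coef(fit)))))
}

# partial-F p-value for the difference between nested fits
partial_f_p <- function(rss0, rss1, df1) {
  if (df1 <= 0) return(NA_real_)
  scale <- rss1 / df1
  if (scale <= .Machine$double.eps * max(rss0, 1)) {
    # saturated smaller model: adding the term either helps (p = 0) or not
    return(if (rss0 - rss1 > .Machine$double.eps * max(rss0, 1)) 0 else 1)
  }
  f <- (rss0 - rss1) / scale
  stats::pf(max(f, 0), 1, df1, lower.tail = FALSE)
}

#' Stepwise ordinary least squares with partial-F entry and removal
#'
#' Classical forward selection with backward elimination: at each entry step
#' the candidate with the smallest partial-F p-value joins if that p-value is
#' at most `p_enter`; after each entry any retained predictor whose partial-F
#' p-value exceeds `p_remove` is eliminated (largest first). Ties at entry are
#' broken by larger |t|, then lexicographic name. `p_enter < p_remove`
#' guarantees termination. A candidate that is perfectly collinear with the
#' current model is skipped with a warning; if no candidate ever qualifies the
#' intercept-only model is returned with a warning.
#'
#' @param data data frame holding the response and candidate columns (e.g.
#'   [candidate_set()] plus a response).
#' @param response response column name.
#' @param candidates candidate column names (default: all other numeric
#'   columns).
#' @param p_enter entry threshold on the partial-F p-value (default 0.05).
#' @param p_remove removal threshold (default 0.10); must exceed `p_enter`.
#' @return object of class `"prediction_model"`: response name, predictors in
#'   entry order, named `coefficients` (with `(Intercept)`), multiple
#'   correlation `r`, `r_squared`, standard error of estimate `see`, `vif`
#'   per retained predictor (1 by convention for a single-predictor model),
#'   `n`, and the underlying `lm` fit.
#' @export
stepwise_ols <- function(data, response, candidates = NULL,
                         p_enter = 0.05, p_remove = 0.10) {
  stopifnot(is.data.frame(data), response %in% names(data))
  if (p_enter >= p_remove) {
    stop("'p_enter' must be strictly below 'p_remove' (prevents cycling)",
         call. = FALSE)
  }
  if (is.null(candidates)) {
    candidates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          response)
  }
  check_columns(data, candidates, "stepwise_ols")
  keep <- stats::complete.cases(data[c(response, candidates)])
  data <- data[keep, , drop = FALSE]
  y <- data[[response]]
  n <- length(y)
  if (n <= length(candidates) + 2) {
    warning("stepwise_ols: development n is small relative to the candidate ",
            "pool; selection may be unstable", call. = FALSE)
  }
  selected <- character(0)
  skipped <- character(0)
  repeat {
    cur <- ols_rss(y, data, selected)
    pool <- setdiff(candidates, selected)
    if (!length(pool)) break
    entry <- data.frame(candidate = pool, p = NA_real_, f = NA_real_)
    for (i in seq_along(pool)) {
      trial <- ols_rss(y, data, c(selected, pool[i]))
      if (length(trial$aliased)) {
        if (!pool[i] %in% skipped) {
          warning(sprintf("candidate '%s' is collinear with the current model; skipped",
                          pool[i]), call. = FALSE)
          skipped <- c(skipped, pool[i])
        }
        next
      }
      entry$p[i] <- partial_f_p(cur$rss, trial$rss, trial$df)
      entry$f[i] <- if (trial$rss / max(trial$df, 1) > 0) {
        (cur$rss - trial$rss) / (trial$rss / trial$df)
      } else Inf
    }
    entry <- entry[!is.na(entry$p), , drop = FALSE]
    if (!nrow(entry)) break
    # smallest p, ties by larger F (|t| = sqrt(F)), then name
    entry <- entry[order(entry$p, -entry$f, entry$candidate,
                         method = "radix"), , drop = FALSE]
    if (entry$p[1] > p_enter) break
    selected <- c(selected, entry$candidate[1])
    # backward elimination pass
    repeat {
      if (!length(selected)) break
      full <- ols_rss(y, data, selected)
      drop_p <- vapply(selected, function(j) {
        red <- ols_rss(y, data, setdiff(selected, j))
        partial_f_p(red$rss, full$rss, full$df)
      }, numeric(1))
      worst <- which.max(drop_p)
      if (drop_p[worst] > p_remove) {
        selected <- selected[-worst]
      } else break
    }
  }
  if (!length(selected)) {
    warning("stepwise_ols: no candidate met the entry criterion; ",
            "returning the intercept-only model", call. = FALSE)
    fit <- stats::lm(y ~ 1)
    coefs <- stats::coef(fit)
    r2 <- 0
  } else {
    fit <- ols_rss(y, data, selected)$fit
    coefs <- stats::coef(fit)
    r2 <- summary(fit)$r.squared
  }
  see <- summary(fit)$sigma
  vifs <- if (length(selected) >= 2) {
    vif(data, selected)
  } else if (length(selected) == 1) {
    stats::setNames(1, selected)  # single-predictor convention
  } else {
    numeric(0)
  }
  structure(list(response = response,
                 predictors = selected,
                 coefficients = coefs,
                 r = sqrt(r2),
                 r_squared = r2,
                 see = see,
                 vif = vifs,
                 n = n,
                 p_enter = p_enter,
                 p_remove = p_remove,
                 fit = fit),
            class = "prediction_model")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from regressing predictor `j`
#' on the remaining predictors (with intercept). Exactly collinear predictors
#' are reported as `Inf`. The conventional multicollinearity cut-off of 5 is
#' attached as attribute `flagged`.
#'
#' @param data data frame holding the predictor columns.
#' @param predictors at least two predictor column names.
#' @param cutoff flagging threshold (default 5).
#' @return named numeric vector of VIFs with logical attribute `flagged`.
#' @export
vif <- function(data, predictors, cutoff = 5) {
  stopifnot(length(predictors) >= 2)
  check_columns(data, predictors, "vif")
  out <- vapply(predictors, function(j) {
    fit <- stats::lm(stats::reformulate(setdiff(predictors, j), response = j),
                     data = data)
    r2 <- summary(fit)$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  attr(out, "flagged") <- out >= cutoff
  out
}

#' Residual diagnostics for a fitted prediction model
#'
#' Normality of residuals by a Kolmogorov-Smirnov test against the normal
#' distribution with the residuals' own mean and standard deviation, plus a
#' variance-homogeneity check: the t-test on the slope of |residual| regressed
#' on fitted values (a significant slope indicates heteroscedasticity). An
#' exact fit (all-zero residuals) is reported as degenerate rather than
#' crashing.
#'
#' @param model a `"prediction_model"` from [stepwise_ols()].
#' @return list: `n`, `residual_mean`, `ks_statistic`, `ks_p`,
#'   `homogeneity_slope`, `homogeneity_p`, `degenerate`.
#' @export
fit_diagnostics <- function(model) {
  stopifnot(inherits(model, "prediction_model"))
  r <- stats::residuals(model$fit)
  ftd <- stats::fitted(model$fit)
  if (all(abs(r) < 1e-12) || stats::sd(r) == 0) {
    return(list(n = length(r), residual_mean = 0,
                ks_statistic = NA_real_, ks_p = NA_real_,
                homogeneity_slope = NA_real_, homogeneity_p = NA_real_,
                degenerate = TRUE))
  }
  ks <- suppressWarnings(stats::ks.test(r, "pnorm", mean(r), stats::sd(r)))
  if (stats::sd(ftd) > 1e-10 * (abs(mean(ftd)) + 1)) {
    hs <- summary(stats::lm(abs(r) ~ ftd))$coefficients
    hom_slope <- unname(hs[2, 1])
    hom_p <- unname(hs[2, 4])
  } else {
    # constant fitted values (e.g. intercept-only model): no slope to test
    hom_slope <- NA_real_
    hom_p <- NA_real_
  }
  list(n = length(r),
       residual_mean = mean(r),
       ks_statistic = unname(ks$statistic),
       ks_p = ks$p.value,
       homogeneity_slope = hom_slope,
       homogeneity_p = hom_p,
       degenerate = FALSE)
}

#' Render a fitted model as a human-readable equation string
#' @param model a `"prediction_model"`.
#' @param digits coefficient digits (default 3, the registry convention).
#' @return single character string.
#' @export
equation_string <- function(model, digits = 3) {
  co <- model$coefficients
  terms <- sprintf("%s %.*f × %s",
                   ifelse(co[-1] < 0, "−", "+"), digits,
                   abs(co[-1]), names(co)[-1])
  paste0(model$response, " = ", sprintf("%.*f", digits, co[1]),
         if (length(terms)) paste0(" ", paste(terms, collapse = " ")) else "")
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("Stepwise OLS prediction model for '%s' (n = %d)\n",
              x$response, x$n))
  cat(sprintf("  R = %.3f, R^2 = %.3f, SEE = %.3f\n", x$r, x$r_squared, x$see))
  if (length(x$predictors)) {
    cat("  predictors (entry order):", paste(x$predictors, collapse = ", "), "\n")
    cat("  VIF:", paste(sprintf("%s=%.2f", names(x$vif), x$vif),
                        collapse = ", "), "\n")
  } else {
    cat("  intercept-only model\n")
  }
  cat("  ", equation_string(x), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted prediction model
#' @param object a `"prediction_model"`.
#' @param newdata data frame with the model's predictor columns (e.g. from
#'   [candidate_set()]).
#' @param ... unused.
#' @return numeric vector of predictions (not floored: raw OLS output).
#' @export
predict.prediction_model <- function(object, newdata, ...) {
  check_columns(newdata, object$predictors, "predict.prediction_model")
  co <- object$coefficients
  if (!length(object$predictors)) return(rep(co[["(Intercept)"]], nrow(newdata)))
  x <- as.matrix(newdata[, object$predictors, drop = FALSE])
  storage.mode(x) <- "double"
  drop(x %*% co[object$predictors]) + co[["(Intercept)"]]
}
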
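#' Reference group statistics for elite male soccer players
#'
#' Published descriptive statistics (mean and standard deviation per variable)
#' for an elite male professional soccer cohort measured with ISAK
#' anthropometry and 50 kHz hand-to-foot BIA, split into an equation
#' development group (n = 117) and a cross-validation group (n = 59). These
#' statistics parameterize the synthetic-cohort generator defaults and the
#' worked examples: because ordinary least squares with an intercept fits the
#' response mean at the predictor means, the bundled prediction equations can
#' be checked directly against these group means.
#'
#' The printed stature SD (0.5 cm) is implausibly small for over a hundred
#' adults and is kept here verbatim as data; the simulator substitutes a
#' realistic default (see [cohort_spec()]).
#'
#' @param group `"development"` or `"validation"`.
#' @return data frame with columns `variable`, `mean`, `sd`; the group size is
#'   attached as attribute `n`.
#' @export
#' @examples
#' soccer_reference_stats("development")
soccer_reference_stats <- function(group = c("development", "validation")) {
  group <- match.arg(group)
  vars <- c("age", "weight_kg", "stature_cm", "bmi", "resistance_ohm",
            "reactance_ohm", "phase_angle", "ffm_kg", "fm_kg", "fm_percent",
            "triceps_mm", "subscapular_mm", "supraspinal_mm", "medial_calf_mm",
            "arm_girth_cm", "calf_girth_cm", "humerus_cm", "femur_cm",
            "endomorphy", "mesomorphy", "ectomorphy")
  dev_mean <- c(27.4, 79.5, 183.8, 23.5, 464.3, 63.8, 7.9, 68.8, 10.6, 13.3,
                6.1, 9.5, 6.7, 5.4, 33.1, 37.9, 7.2, 10.2, 2.0, 4.9, 2.7)
  dev_sd   <- c(4.3, 6.1, 0.5, 1.2, 37.1, 5.7, 0.5, 5.4, 1.7, 1.9,
                1.7, 1.7, 1.8, 1.4, 1.7, 1.7, 0.4, 0.5, 0.4, 0.8, 0.6)
  val_mean <- c(28.0, 78.9, 182.9, 23.6, 456.8, 64.6, 8.1, 68.7, 10.2, 12.9,
                5.6, 9.6, 6.4, 5.0, 33.3, 38.2, 7.2, 10.3, 1.9, 5.2, 2.7)
  val_sd   <- c(5.0, 6.5, 0.5, 1.3, 33.3, 6.6, 0.9, 5.7, 1.9, 1.9,
                1.2, 1.7, 1.7, 0.9, 1.5, 3.4, 0.3, 0.5, 0.4, 0.8, 0.6)
  out <- if (group == "development") {
    data.frame(variable = vars, mean = dev_mean, sd = dev_sd)
  } else {
    data.frame(variable = vars, mean = val_mean, sd = val_sd)
  }
  attr(out, "n") <- if (group == "development") 117L else 59L
  out
}

#' Somatotype prediction equation registry
#'
#' Versioned registry of reduced-measurement somatotype prediction equations.
#' Each set records the population, device and measurement frequency it was
#' developed on, together with intercept and coefficients (stored exactly to
#' their published precision) for each somatotype component. The bundled set
#' `"soccer_male_50khz"` predicts, for elite male soccer players measured with
#' hand-to-foot single-frequency BIA at 50 kHz:
#'
#' * endomorphy from fat mass percentage, the bioimpedance index
#'   (stature cm squared / resistance ohm), triceps and supraspinal skinfolds
#'   (mm) and stature (cm);
#' * mesomorphy from contracted arm girth, calf girth (cm), fat-free mass (kg)
#'   and stature (cm);
#' * ectomorphy from the fat-free mass / stature ratio (kg/cm) and stature
#'   (cm).
#'
#' These equations need no breadths, no subscapular or medial calf skinfolds
#' and no reactance, which is the measurement reduction the package exists to
#' support.
#'
#' @param set equation set identifier.
#' @return a list with elements `id`, `population`, `device`, `frequency_khz`
#'   and one element per component holding `intercept` and a named
#'   `coefficients` vector (names are predictor column names in the candidate
#'   table, see [candidate_set()]).
#' @export
#' @examples
#' eq <- somatotype_equations()
#' eq$ectomorphy
somatotype_equations <- function(set = "soccer_male_50khz") {
  registry <- list(
    soccer_male_50khz = list(
      id = "soccer_male_50khz",
      population = "elite male professional soccer players",
      device = "hand-to-foot single-frequency BIA",
      frequency_khz = 50,
      sex = "male",
      endomorphy = list(
        intercept = 4.292,
        coefficients = c(fm_percent = 0.050, s2_resistance = 0.012,
                         triceps_mm = 0.092, supraspinal_mm = 0.139,
                         stature_cm = -0.029)),
      mesomorphy = list(
        intercept = 10.351,
        coefficients = c(arm_girth_cm = 0.212, calf_girth_cm = 0.187,
                         ffm_kg = 0.048, stature_cm = -0.125)),
      ectomorphy = list(
        intercept = -7.945,
        coefficients = c(ffm_stature = -25.021, stature_cm = 0.109))
    )
  )
  if (!set %in% names(registry)) {
    stop(sprintf("unknown equation set '%s'; available: %s",
                 set, paste(names(registry), collapse = ", ")), call. = FALSE)
  }
  registry[[set]]
}

# evaluate one registry equation on a data frame of predictor columns,
# flooring at the somatotype rating floor; attaches a logical 'floored' attr
eval_equation <- function(eq, data, floor_at = 0.1) {
  check_columns(data, names(eq$coefficients), "eval_equation")
  x <- as.matrix(data[, names(eq$coefficients), drop = FALSE])
  storage.mode(x) <- "double"
  raw <- drop(x %*% eq$coefficients) + eq$intercept
  floored <- raw < floor_at
  out <- pmax(raw, floor_at)
  attr(out, "floored") <- floored
  out
}
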
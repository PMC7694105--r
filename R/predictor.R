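# Reduced-measurement somatotype prediction: the bundled equations estimate
# all three components from weight, stature, resistance, two skinfolds and
# two girths -- no breadths, no subscapular or medial calf skinfold, no
# reactance.

#' Predict endomorphy from BIA-derived and reduced anthropometric inputs
#'
#' Linear equation (registry set `"soccer_male_50khz"`):
#' `4.292 + 0.050 FM% + 0.012 S^2/R + 0.092 triceps + 0.139 supraspinal
#'  - 0.029 stature`, floored at 0.1 like reference ratings.
#'
#' @param fm_percent fat mass percentage.
#' @param s2_resistance bioimpedance index, cm^2/ohm.
#' @param triceps_mm,supraspinal_mm skinfolds, mm.
#' @param stature_cm stature, cm.
#' @param equations equation registry entry, see [somatotype_equations()].
#' @return predicted endomorphy rating (floored at 0.1); attribute `floored`
#'   marks elements where the floor engaged.
#' @export
#' @examples
#' predict_endomorphy(13.3, 183.8^2 / 464.3, 6.1, 6.7, 183.8)  # 2.0 to 1 d.p.
predict_endomorphy <- function(fm_percent, s2_resistance, triceps_mm,
                               supraspinal_mm, stature_cm,
                               equations = somatotype_equations()) {
  check_nonneg(fm_percent, "fm_percent")
  if (any(fm_percent >= 100)) stop("'fm_percent' must be < 100", call. = FALSE)
  check_nonneg(s2_resistance, "s2_resistance")
  check_nonneg(triceps_mm, "triceps_mm")
  check_nonneg(supraspinal_mm, "supraspinal_mm")
  check_positive(stature_cm, "stature_cm")
  eval_equation(equations$endomorphy,
                data.frame(fm_percent = fm_percent,
                           s2_resistance = s2_resistance,
                           triceps_mm = triceps_mm,
                           supraspinal_mm = supraspinal_mm,
                           stature_cm = stature_cm))
}

#' Predict mesomorphy from girths, fat-free mass and stature
#'
#' Linear equation (registry set `"soccer_male_50khz"`):
#' `10.351 + 0.212 CAC + 0.187 CC + 0.048 FFM - 0.125 stature`, floored at
#' 0.1. CAC is the contracted arm girth and CC the calf girth, both in cm and
#' uncorrected for skinfolds.
#'
#' @param arm_girth_cm contracted arm girth, cm.
#' @param calf_girth_cm calf girth, cm.
#' @param ffm_kg fat-free mass, kg.
#' @param stature_cm stature, cm.
#' @param equations equation registry entry.
#' @return predicted mesomorphy rating (floored at 0.1), `floored` attribute
#'   as in [predict_endomorphy()].
#' @export
predict_mesomorphy <- function(arm_girth_cm, calf_girth_cm, ffm_kg,
                               stature_cm,
                               equations = somatotype_equations()) {
  check_nonneg(arm_girth_cm, "arm_girth_cm")
  check_nonneg(calf_girth_cm, "calf_girth_cm")
  check_nonneg(ffm_kg, "ffm_kg")
  check_nonneg(stature_cm, "stature_cm")
  eval_equation(equations$mesomorphy,
                data.frame(arm_girth_cm = arm_girth_cm,
                           calf_girth_cm = calf_girth_cm,
                           ffm_kg = ffm_kg,
                           stature_cm = stature_cm))
}

#' Predict ectomorphy from fat-free mass and stature
#'
#' Linear equation (registry set `"soccer_male_50khz"`):
#' `-7.945 - 25.021 FFM/S + 0.109 stature`, floored at 0.1. The `FFM/S` ratio
#' uses stature in cm (kg/cm), the unit in which the equation reproduces the
#' development-group mean.
#'
#' @param ffm_kg fat-free mass, kg.
#' @param stature_cm stature, cm.
#' @param equations equation registry entry.
#' @return predicted ectomorphy rating (floored at 0.1), `floored` attribute
#'   as in [predict_endomorphy()].
#' @export
#' @examples
#' predict_ectomorphy(68.8, 183.8)  # 2.7 to 1 d.p.
predict_ectomorphy <- function(ffm_kg, stature_cm,
                               equations = somatotype_equations()) {
  check_nonneg(ffm_kg, "ffm_kg")
  check_positive(stature_cm, "stature_cm")
  eval_equation(equations$ectomorphy,
                data.frame(ffm_stature = ffm_kg / stature_cm,
                           stature_cm = stature_cm))
}

#' Predict the full somatotype from BIA plus reduced anthropometry
#'
#' The package's headline operation: chains the BIA body-composition equations
#' (fat-free mass, fat mass percentage, bioimpedance index) into the three
#' reduced-measurement somatotype equations. Only weight, stature, resistance,
#' triceps and supraspinal skinfolds and the two girths are used -- no bone
#' breadths, no subscapular or medial calf skinfold, and no reactance --
#' which is the measurement reduction relative to the full Heath-Carter
#' protocol. All intermediates are returned alongside the predictions.
#'
#' @param cohort cohort data frame; `reactance_ohm` may be missing or `NA`
#'   (it is only needed for phase-angle reporting, not for prediction).
#' @param equations equation registry entry, see [somatotype_equations()].
#' @return data frame: `athlete_id` (when present), intermediates
#'   (`s2_resistance`, `ffm_kg`, `fm_kg`, `fm_percent`, and `phase_angle`
#'   where reactance is available), predicted `endomorphy`, `mesomorphy`,
#'   `ectomorphy` (full precision, floored at 0.1), `floored` (comma-joined
#'   names of components where the floor engaged, `""` otherwise), `category`,
#'   `chart_x`, `chart_y`.
#' @export
predict_somatotype <- function(cohort, equations = somatotype_equations()) {
  check_columns(cohort, c("weight_kg", "stature_cm", "resistance_ohm",
                          "triceps_mm", "supraspinal_mm",
                          "arm_girth_cm", "calf_girth_cm"),
                "predict_somatotype")
  n <- nrow(cohort)
  out <- data.frame(row.names = seq_len(n))
  if ("athlete_id" %in% names(cohort)) out$athlete_id <- cohort$athlete_id
  if (n == 0L) {
    for (cl in c("s2_resistance", "ffm_kg", "fm_kg", "fm_percent",
                 "phase_angle", "endomorphy", "mesomorphy", "ectomorphy",
                 "chart_x", "chart_y")) out[[cl]] <- numeric(0)
    out$floored <- character(0)
    out$category <- character(0)
    return(out)
  }
  out$s2_resistance <- bioimpedance_index(cohort$stature_cm,
                                          cohort$resistance_ohm)
  out$ffm_kg <- ffm_athlete(cohort$weight_kg, cohort$stature_cm,
                            cohort$resistance_ohm)
  fm <- fat_mass(cohort$weight_kg, out$ffm_kg)
  out$fm_kg <- fm$fm_kg
  out$fm_percent <- fm$fm_percent
  out$phase_angle <- if ("reactance_ohm" %in% names(cohort) &&
                         any(is.finite(cohort$reactance_ohm))) {
    ifelse(is.finite(cohort$reactance_ohm),
           (cohort$reactance_ohm / cohort$resistance_ohm) * 180 / pi,
           NA_real_)
  } else NA_real_
  endo <- predict_endomorphy(out$fm_percent, out$s2_resistance,
                             cohort$triceps_mm, cohort$supraspinal_mm,
                             cohort$stature_cm, equations)
  meso <- predict_mesomorphy(cohort$arm_girth_cm, cohort$calf_girth_cm,
                             out$ffm_kg, cohort$stature_cm, equations)
  ecto <- predict_ectomorphy(out$ffm_kg, cohort$stature_cm, equations)
  fl <- cbind(endomorphy = attr(endo, "floored"),
              mesomorphy = attr(meso, "floored"),
              ectomorphy = attr(ecto, "floored"))
  out$endomorphy <- as.numeric(endo)
  out$mesomorphy <- as.numeric(meso)
  out$ectomorphy <- as.numeric(ecto)
  out$floored <- apply(fl, 1L, function(r) paste(colnames(fl)[r], collapse = ","))
  out$category <- classify_somatotype(out$endomorphy, out$mesomorphy,
                                      out$ectomorphy)
  pt <- somatochart_point(out$endomorphy, out$mesomorphy, out$ectomorphy)
  out$chart_x <- pt$x
  out$chart_y <- pt$y
  attr(out, "equation_set") <- equations$id
  out
}
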
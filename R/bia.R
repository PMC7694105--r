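# Bioelectrical quantities and BIA-derived body composition.
#
# The 50 kHz hand-to-foot measurement context is the assumed default; the
# athlete-specific fat-free mass equation is male-specific and refuses any
# other sex.

#' Bioelectrical phase angle
#'
#' Phase angle in degrees from whole-body resistance and reactance. The
#' default (`method = "ratio"`) computes `(Xc/R) * 180/pi`, the small-angle
#' form used by field equations for athletes; `method = "arctan"` computes the
#' conventional `atan(Xc/R) * 180/pi`. At physiological ratios (Xc/R around
#' 0.14) the two differ by less than 0.1 degree; the difference is documented
#' rather than hidden because downstream prediction equations were developed
#' on the ratio form.
#'
#' @param resistance_ohm whole-body resistance at 50 kHz, ohm.
#' @param reactance_ohm whole-body reactance at 50 kHz, ohm.
#' @param method `"ratio"` (default) or `"arctan"`.
#' @return phase angle, degrees.
#' @export
#' @examples
#' phase_angle(464.3, 63.8)  # 7.9 to 1 d.p.
phase_angle <- function(resistance_ohm, reactance_ohm,
                        method = c("ratio", "arctan")) {
  method <- match.arg(method)
  check_positive(resistance_ohm, "resistance_ohm")
  check_nonneg(reactance_ohm, "reactance_ohm")
  ratio <- reactance_ohm / resistance_ohm
  if (method == "ratio") ratio * 180 / pi else atan(ratio) * 180 / pi
}

#' Bioimpedance index
#'
#' Stature squared over resistance (`cm^2/ohm`), the core conductor-volume
#' predictor of fat-free mass.
#'
#' @param stature_cm stature, cm.
#' @param resistance_ohm resistance, ohm.
#' @return `stature_cm^2 / resistance_ohm`.
#' @export
bioimpedance_index <- function(stature_cm, resistance_ohm) {
  check_positive(stature_cm, "stature_cm")
  check_positive(resistance_ohm, "resistance_ohm")
  stature_cm^2 / resistance_ohm
}

#' Athlete-specific fat-free mass from 50 kHz BIA
#'
#' Male athlete fat-free mass (kg):
#' `FFM = -2.261 + 0.327 * stature^2/R + 0.525 * weight + 5.462`,
#' where the trailing constant is the male sex indicator term (indicator = 1).
#' The equation is male-specific: any other `sex` is refused with an error
#' rather than silently mis-applied.
#'
#' @param weight_kg body mass, kg.
#' @param stature_cm stature, cm.
#' @param resistance_ohm resistance at 50 kHz, ohm.
#' @param sex must be `"male"`.
#' @return fat-free mass, kg.
#' @export
#' @examples
#' ffm_athlete(80, 180, 450)  # 68.745
ffm_athlete <- function(weight_kg, stature_cm, resistance_ohm, sex = "male") {
  if (!identical(unique(sex), "male")) {
    stop("ffm_athlete: the fat-free mass equation is male-specific; ",
         "refusing sex != 'male'", call. = FALSE)
  }
  check_positive(weight_kg, "weight_kg")
  -2.261 + 0.327 * bioimpedance_index(stature_cm, resistance_ohm) +
    0.525 * weight_kg + 5.462
}

#' Fat mass and fat mass percentage
#'
#' `FM = weight - FFM` and `FM% = 100 * FM / weight`. A fat-free mass above
#' body weight is physically impossible and raises an implausible-composition
#' error carrying both values.
#'
#' @param weight_kg body mass, kg.
#' @param ffm_kg fat-free mass, kg.
#' @return data frame with columns `fm_kg` and `fm_percent`.
#' @export
#' @examples
#' fat_mass(80, 68.745)
fat_mass <- function(weight_kg, ffm_kg) {
  check_positive(weight_kg, "weight_kg")
  check_positive(ffm_kg, "ffm_kg")
  bad <- ffm_kg > weight_kg
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(paste0("implausible body composition: fat-free mass (%.3f kg) ",
                        "exceeds body weight (%.3f kg)"),
                 ffm_kg[i], weight_kg[i]), call. = FALSE)
  }
  fm <- weight_kg - ffm_kg
  data.frame(fm_kg = fm, fm_percent = 100 * fm / weight_kg)
}

#' BIA-derived body composition for a cohort table
#'
#' Computes, per athlete: phase angle, the bioimpedance indices
#' `stature^2/R` and `stature^2/Xc`, fat-free mass (athlete-specific male
#' equation), fat mass and fat mass percentage. By construction
#' `ffm_kg + fm_kg` equals body weight exactly. A measurement frequency other
#' than 50 kHz triggers a warning (not an error): the bundled equations were
#' developed at 50 kHz.
#'
#' @param cohort cohort data frame (see [cohort_columns()]).
#' @param frequency_khz declared measurement frequency (default 50).
#' @return the cohort with columns `phase_angle`, `s2_resistance`,
#'   `s2_reactance`, `ffm_kg`, `fm_kg`, `fm_percent` appended.
#' @export
body_composition <- function(cohort, frequency_khz = 50) {
  check_columns(cohort, c("weight_kg", "stature_cm", "resistance_ohm",
                          "reactance_ohm"), "body_composition")
  if (!isTRUE(all.equal(frequency_khz, 50))) {
    warning(sprintf(paste0("declared frequency %s kHz differs from the 50 kHz ",
                           "the bundled equations were developed at; ",
                           "estimates may lose accuracy"), frequency_khz),
            call. = FALSE)
  }
  if (nrow(cohort) == 0L) {
    for (cl in c("phase_angle", "s2_resistance", "s2_reactance", "ffm_kg",
                 "fm_kg", "fm_percent")) cohort[[cl]] <- numeric(0)
    return(cohort)
  }
  cohort$phase_angle <- phase_angle(cohort$resistance_ohm, cohort$reactance_ohm)
  cohort$s2_resistance <- bioimpedance_index(cohort$stature_cm,
                                             cohort$resistance_ohm)
  cohort$s2_reactance <- ifelse(cohort$reactance_ohm > 0,
                                cohort$stature_cm^2 / cohort$reactance_ohm,
                                NA_real_)
  cohort$ffm_kg <- ffm_athlete(cohort$weight_kg, cohort$stature_cm,
                               cohort$resistance_ohm)
  fm <- fat_mass(cohort$weight_kg, cohort$ffm_kg)
  cohort$fm_kg <- fm$fm_kg
  cohort$fm_percent <- fm$fm_percent
  cohort
}
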
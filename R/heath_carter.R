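# Reference Heath-Carter anthropometric somatotype engine.
#
# The three component formulas use the standard published Heath-Carter
# constants. All functions are vectorized over athletes; ratings are floored
# at 0.1 by convention.

SOMATOTYPE_FLOOR <- 0.1

#' Heath-Carter endomorphy (height-corrected)
#'
#' Relative adiposity from three skinfolds with a height correction: with
#' `X = (triceps + subscapular + supraspinal) * 170.18 / stature`,
#' `endomorphy = -0.7182 + 0.1451 X - 0.00068 X^2 + 0.0000014 X^3`,
#' floored at 0.1.
#'
#' @param triceps_mm,subscapular_mm,supraspinal_mm skinfold thicknesses, mm.
#' @param stature_cm stature, cm.
#' @return endomorphy rating (>= 0.1), full precision.
#' @export
#' @examples
#' endomorphy_reference(6.1, 9.5, 6.7, 183.8)  # 2.0 to 1 d.p.
endomorphy_reference <- function(triceps_mm, subscapular_mm, supraspinal_mm,
                                 stature_cm) {
  check_positive(triceps_mm, "triceps_mm")
  check_positive(subscapular_mm, "subscapular_mm")
  check_positive(supraspinal_mm, "supraspinal_mm")
  check_positive(stature_cm, "stature_cm")
  x <- (triceps_mm + subscapular_mm + supraspinal_mm) * 170.18 / stature_cm
  rating <- -0.7182 + 0.1451 * x - 0.00068 * x^2 + 0.0000014 * x^3
  pmax(rating, SOMATOTYPE_FLOOR)
}

#' Heath-Carter mesomorphy
#'
#' Musculoskeletal robustness from bone breadths and skinfold-corrected limb
#' girths relative to stature:
#' `0.858 HB + 0.601 FB + 0.188 (CAG - triceps/10) + 0.161 (CG - calf_sf/10)
#'  - 0.131 stature + 4.5`, floored at 0.1. Skinfolds are converted from mm
#' to cm for the girth correction.
#'
#' @param humerus_cm,femur_cm bone breadths, cm.
#' @param arm_girth_cm contracted arm girth, cm.
#' @param triceps_mm triceps skinfold, mm.
#' @param calf_girth_cm calf girth, cm.
#' @param medial_calf_mm medial calf skinfold, mm.
#' @param stature_cm stature, cm.
#' @return mesomorphy rating (>= 0.1), full precision.
#' @export
#' @examples
#' mesomorphy_reference(7.2, 10.2, 33.1, 6.1, 37.9, 5.4, 183.8)  # 4.9 to 1 d.p.
mesomorphy_reference <- function(humerus_cm, femur_cm, arm_girth_cm,
                                 triceps_mm, calf_girth_cm, medial_calf_mm,
                                 stature_cm) {
  check_positive(humerus_cm, "humerus_cm")
  check_positive(femur_cm, "femur_cm")
  check_positive(arm_girth_cm, "arm_girth_cm")
  check_positive(triceps_mm, "triceps_mm")
  check_positive(calf_girth_cm, "calf_girth_cm")
  check_positive(medial_calf_mm, "medial_calf_mm")
  check_positive(stature_cm, "stature_cm")
  cag <- arm_girth_cm - triceps_mm / 10
  cg <- calf_girth_cm - medial_calf_mm / 10
  check_positive(cag, "skinfold-corrected arm girth")
  check_positive(cg, "skinfold-corrected calf girth")
  rating <- 0.858 * humerus_cm + 0.601 * femur_cm + 0.188 * cag +
    0.161 * cg - 0.131 * stature_cm + 4.5
  pmax(rating, SOMATOTYPE_FLOOR)
}

#' Heath-Carter ectomorphy
#'
#' Relative linearity via the height-weight ratio `HWR = stature / weight^(1/3)`
#' (stature cm, weight kg), with the standard piecewise rule on half-closed
#' intervals: `HWR >= 40.75` uses `0.732 HWR - 28.58`;
#' `38.25 < HWR < 40.75` uses `0.463 HWR - 17.63`; `HWR <= 38.25` is floored
#' at 0.1.
#'
#' @param stature_cm stature, cm.
#' @param weight_kg body mass, kg.
#' @return ectomorphy rating (>= 0.1), full precision.
#' @export
#' @examples
#' ectomorphy_reference(183.8, 79.5)  # 2.7 to 1 d.p.
ectomorphy_reference <- function(stature_cm, weight_kg) {
  check_positive(stature_cm, "stature_cm")
  check_positive(weight_kg, "weight_kg")
  hwr <- stature_cm / weight_kg^(1 / 3)
  rating <- ifelse(hwr >= 40.75, 0.732 * hwr - 28.58,
                   ifelse(hwr > 38.25, 0.463 * hwr - 17.63, SOMATOTYPE_FLOOR))
  pmax(rating, SOMATOTYPE_FLOOR)
}

#' Classify a somatotype into one of the thirteen standard categories
#'
#' Deterministic classification with the half-unit convention: a component is
#' *dominant* when it exceeds both others by more than 0.5 units, and two
#' components are *equal* when they differ by at most 0.5 units. A dominant
#' component with the other two equal gives a "balanced" type; a dominant
#' component with an ordered remainder gives a modifier form (e.g.
#' "ectomorphic mesomorph"); two equal leaders above the third give a hyphened
#' hybrid (e.g. "mesomorph-ectomorph"); everything else, including exact
#' three-way ties, is "central". Exact boundary ties therefore fall toward the
#' balanced/hybrid/central labels.
#'
#' @param endomorphy,mesomorphy,ectomorphy rating vectors (recycled).
#' @return character vector of category labels.
#' @export
#' @examples
#' classify_somatotype(2.0, 4.9, 2.7)  # "ectomorphic mesomorph"
classify_somatotype <- function(endomorphy, mesomorphy, ectomorphy) {
  n <- max(length(endomorphy), length(mesomorphy), length(ectomorphy))
  e <- rep_len(endomorphy, n); m <- rep_len(mesomorphy, n)
  c_ <- rep_len(ectomorphy, n)
  comp_names <- c("endomorph", "mesomorph", "ectomorph")
  one <- function(e, m, c_) {
    v <- c(endomorph = e, mesomorph = m, ectomorph = c_)
    if (any(!is.finite(v))) return(NA_character_)
    ord <- order(v, decreasing = TRUE)
    a <- v[ord[1]]; b <- v[ord[2]]; d <- v[ord[3]]
    if (a - b > 0.5) {                       # single dominant component
      dom <- names(v)[ord[1]]
      if (b - d <= 0.5) {
        paste("balanced", dom)
      } else {
        paste0(names(v)[ord[2]], "ic ", dom)
      }
    } else if (b - d > 0.5) {                # two equal leaders
      lead <- sort(match(names(v)[ord[1:2]], comp_names))
      paste(comp_names[lead], collapse = "-")
    } else {
      "central"
    }
  }
  vapply(seq_len(n), function(i) one(e[i], m[i], c_[i]), character(1))
}

#' Somatochart projection of a somatotype
#'
#' Standard two-dimensional somatochart coordinates:
#' `x = ectomorphy - endomorphy`, `y = 2 mesomorphy - (endomorphy +
#' ectomorphy)`.
#'
#' @param endomorphy,mesomorphy,ectomorphy rating vectors.
#' @return data frame with columns `x` and `y`.
#' @export
#' @examples
#' somatochart_point(2.0, 4.9, 2.7)
somatochart_point <- function(endomorphy, mesomorphy, ectomorphy) {
  data.frame(x = ectomorphy - endomorphy,
             y = 2 * mesomorphy - (endomorphy + ectomorphy))
}

#' Reference somatotype for a cohort table
#'
#' Applies the three Heath-Carter component formulas to every athlete and
#' appends the ratings, category and somatochart coordinates to the cohort.
#'
#' @param cohort cohort data frame (see [cohort_columns()]).
#' @return the cohort with columns `endomorphy`, `mesomorphy`, `ectomorphy`
#'   (full precision), `category`, `chart_x`, `chart_y` appended.
#' @export
somatotype_reference <- function(cohort) {
  check_columns(cohort, c("weight_kg", "stature_cm", "triceps_mm",
                          "subscapular_mm", "supraspinal_mm", "medial_calf_mm",
                          "arm_girth_cm", "calf_girth_cm", "humerus_cm",
                          "femur_cm"), "somatotype_reference")
  if (nrow(cohort) == 0L) {
    cohort$endomorphy <- cohort$mesomorphy <- cohort$ectomorphy <- numeric(0)
    cohort$category <- character(0)
    cohort$chart_x <- cohort$chart_y <- numeric(0)
    return(cohort)
  }
  endo <- endomorphy_reference(cohort$triceps_mm, cohort$subscapular_mm,
                               cohort$supraspinal_mm, cohort$stature_cm)
  meso <- mesomorphy_reference(cohort$humerus_cm, cohort$femur_cm,
                               cohort$arm_girth_cm, cohort$triceps_mm,
                               cohort$calf_girth_cm, cohort$medial_calf_mm,
                               cohort$stature_cm)
  ecto <- ectomorphy_reference(cohort$stature_cm, cohort$weight_kg)
  pt <- somatochart_point(endo, meso, ecto)
  cohort$endomorphy <- endo
  cohort$mesomorphy <- meso
  cohort$ectomorphy <- ecto
  cohort$category <- classify_somatotype(endo, meso, ecto)
  cohort$chart_x <- pt$x
  cohort$chart_y <- pt$y
  cohort
}

#' Propagate technical error of measurement into somatotype uncertainty
#'
#' Optional Monte-Carlo utility: perturbs skinfolds, girths and breadths with
#' multiplicative Gaussian noise at the stated technical error of measurement
#' (ISAK level-1 defaults: 5% for skinfolds, 1% for girths and breadths),
#' recomputes the reference somatotype for each replicate, and reports the
#' per-athlete standard deviation of each component. Off by default in every
#' pipeline; purely exploratory.
#'
#' @param cohort cohort data frame.
#' @param n_replicates number of perturbed replicates (default 100).
#' @param tem_skinfold,tem_girth,tem_breadth relative technical errors.
#' @param seed integer seed (required; all randomness in the package is
#'   explicitly seeded).
#' @return data frame: `athlete_id`, `endomorphy_sd`, `mesomorphy_sd`,
#'   `ectomorphy_sd`.
#' @export
somatotype_measurement_error <- function(cohort, n_replicates = 100,
                                         tem_skinfold = 0.05,
                                         tem_girth = 0.01,
                                         tem_breadth = 0.01, seed) {
  stopifnot(n_replicates >= 2, !missing(seed))
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  sf_cols <- c("triceps_mm", "subscapular_mm", "supraspinal_mm", "medial_calf_mm")
  g_cols <- c("arm_girth_cm", "calf_girth_cm")
  b_cols <- c("humerus_cm", "femur_cm")
  draws <- array(NA_real_, dim = c(n, 3L, n_replicates))
  for (k in seq_len(n_replicates)) {
    pert <- cohort
    for (cl in sf_cols) pert[[cl]] <- pmax(pert[[cl]] * (1 + stats::rnorm(n, 0, tem_skinfold)), 0.1)
    for (cl in g_cols) pert[[cl]] <- pert[[cl]] * (1 + stats::rnorm(n, 0, tem_girth))
    for (cl in b_cols) pert[[cl]] <- pert[[cl]] * (1 + stats::rnorm(n, 0, tem_breadth))
    s <- somatotype_reference(pert)
    draws[, , k] <- cbind(s$endomorphy, s$mesomorphy, s$ectomorphy)
  }
  data.frame(athlete_id = cohort$athlete_id,
             endomorphy_sd = apply(draws[, 1L, , drop = FALSE], 1L, stats::sd),
             mesomorphy_sd = apply(draws[, 2L, , drop = FALSE], 1L, stats::sd),
             ectomorphy_sd = apply(draws[, 3L, , drop = FALSE], 1L, stats::sd))
}
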
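# Synthetic elite-soccer cohort generator.
#
# Variables are drawn from a truncated correlated Gaussian parameterized by
# the bundled reference group statistics. In "linked" mode the bioimpedance
# side is derived from the anthropometric side: a latent fat-free mass target
# is drawn jointly with the anthropometrics and resistance is back-solved
# from the athlete FFM equation, so that anthropometry and BIA are mutually
# consistent by construction.

# generation variables, in draw order
GEN_VARS <- c("age", "weight_kg", "stature_cm",
              "triceps_mm", "subscapular_mm", "supraspinal_mm",
              "medial_calf_mm", "arm_girth_cm", "calf_girth_cm",
              "humerus_cm", "femur_cm",
              "ffm_kg", "phase_angle", "resistance_ohm", "reactance_ohm")

#' Default correlation matrix for the synthetic cohort
#'
#' A hand-set, documented, positive-definite correlation matrix over the
#' fifteen generation variables, shipped as an editable CSV
#' (`extdata/cohort_correlation_default.csv`). Key choices: weight-FFM 0.95,
#' weight-stature 0.5, skinfold-skinfold 0.6, skinfolds independent of FFM,
#' girths loading on both weight and FFM, and resistance negatively
#' correlated with FFM and weight (conductor volume). The matrix encodes
#' plausible kinanthropometric structure, not an estimate from any dataset.
#'
#' @param path optional path to an alternative correlation CSV (same layout:
#'   first column `variable`, then one column per variable).
#' @return named 15 x 15 correlation matrix.
#' @export
default_correlation <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_correlation_default.csv",
                        package = "somatoBIA", mustWork = TRUE)
  }
  raw <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  storage.mode(m) <- "double"
  m[GEN_VARS, GEN_VARS]
}

#' Specification of a synthetic cohort
#'
#' Bundles everything [generate_cohort()] needs: size, per-variable means and
#' SDs (defaults: the development-group reference statistics, except stature
#' SD which defaults to a realistic 5 cm), the correlation matrix, the
#' playing-position mix (defaults to the 8/50/62/56 roster proportions of a
#' full squad listing), the generation mode and the seed.
#'
#' In `"linked"` mode resistance is back-solved from the latent fat-free mass
#' target via `R = 0.327 * S^2 / (FFM + 2.261 - 0.525 W - 5.462)` and
#' reactance from the drawn phase angle (`Xc = R * PhA * pi/180`), so
#' [ffm_athlete()] recovers the target exactly. In `"empirical"` mode
#' resistance and reactance are drawn directly from their marginal moments.
#'
#' @param n cohort size (>= 0).
#' @param mode `"linked"` (default) or `"empirical"`.
#' @param means,sds optional named numeric overrides for any of the
#'   generation variables (see the `variable` column of
#'   [soccer_reference_stats()]; `phase_angle`, `ffm_kg`, `resistance_ohm`,
#'   `reactance_ohm` are latent inputs in linked mode).
#' @param correlation optional correlation matrix over the generation
#'   variables; must be symmetric positive-definite with unit diagonal.
#' @param position_mix named proportions over [position_levels()], summing
#'   to 1.
#' @param seed integer seed.
#' @return object of class `"cohort_spec"`.
#' @export
#' @examples
#' spec <- cohort_spec(n = 20, seed = 42)
#' cohort <- generate_cohort(spec)
cohort_spec <- function(n, mode = c("linked", "empirical"),
                        means = NULL, sds = NULL, correlation = NULL,
                        position_mix = NULL, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n), n >= 0)
  stats <- soccer_reference_stats("development")
  mu <- stats::setNames(stats$mean, stats$variable)[GEN_VARS]
  sig <- stats::setNames(stats$sd, stats$variable)[GEN_VARS]
  sig["stature_cm"] <- 5.0  # realistic adult stature SD; printed 0.5 is not
  if (!is.null(means)) {
    unknown <- setdiff(names(means), GEN_VARS)
    if (length(unknown)) stop("unknown mean override(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    mu[names(means)] <- means
  }
  if (!is.null(sds)) {
    unknown <- setdiff(names(sds), GEN_VARS)
    if (length(unknown)) stop("unknown sd override(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    sig[names(sds)] <- sds
  }
  if (any(sig <= 0)) stop("all SDs must be positive", call. = FALSE)
  if (is.null(correlation)) correlation <- default_correlation()
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      !isTRUE(all.equal(unname(diag(correlation)), rep(1, length(GEN_VARS))))) {
    stop("correlation matrix must be symmetric with unit diagonal",
         call. = FALSE)
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("correlation matrix is not positive-definite (smallest eigenvalue %.3e)",
                 min(ev)), call. = FALSE)
  }
  if (is.null(position_mix)) {
    position_mix <- c(goalkeeper = 8, defender = 50, midfielder = 62,
                      forward = 56) / 176
  }
  stopifnot(setequal(names(position_mix), position_levels()))
  if (!isTRUE(all.equal(sum(position_mix), 1))) {
    stop("position_mix proportions must sum to 1", call. = FALSE)
  }
  structure(list(n = as.integer(n), mode = mode, means = mu, sds = sig,
                 correlation = correlation,
                 position_mix = position_mix[position_levels()],
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# physiological acceptance test for a matrix of candidate draws
valid_draws <- function(z, mode) {
  ok <- is.finite(rowSums(z))
  ok <- ok & z[, "age"] > 15 & z[, "weight_kg"] > 0
  ok <- ok & z[, "stature_cm"] >= 100 & z[, "stature_cm"] <= 230
  for (cl in c("triceps_mm", "subscapular_mm", "supraspinal_mm",
               "medial_calf_mm")) {
    ok <- ok & z[, cl] > 0 & z[, cl] < 60
  }
  ok <- ok & z[, "arm_girth_cm"] > z[, "triceps_mm"] / 10
  ok <- ok & z[, "calf_girth_cm"] > z[, "medial_calf_mm"] / 10
  ok <- ok & z[, "humerus_cm"] > 0 & z[, "femur_cm"] > 0
  ok <- ok & z[, "ffm_kg"] > 0 & z[, "ffm_kg"] < z[, "weight_kg"]
  ok <- ok & z[, "phase_angle"] > 0 & z[, "phase_angle"] < 20
  if (mode == "linked") {
    # back-solve denominator must stay positive for a positive resistance,
    # with margin so rounding weight to 0.1 kg cannot flip its sign
    ok <- ok & (z[, "ffm_kg"] + 2.261 - 0.525 * z[, "weight_kg"] - 5.462) > 0.5
  } else {
    ok <- ok & z[, "resistance_ohm"] > 0 & z[, "reactance_ohm"] > 0 &
      z[, "reactance_ohm"] < z[, "resistance_ohm"]
  }
  ok
}

#' Generate a synthetic cohort
#'
#' Draws athletes from the truncated correlated Gaussian defined by a
#' [cohort_spec()]: candidate rows are sampled from the multivariate normal
#' and rows violating the physiological record invariants (or, in linked
#' mode, the resistance back-solve constraint) are rejected and redrawn.
#' Anthropometric outputs are rounded to instrument precision (0.1 units)
#' *before* the linked back-solve, so the fat-free mass inversion identity
#' holds exactly on the emitted table. Output is byte-identical for identical
#' spec and seed.
#'
#' @param spec a [cohort_spec()].
#' @return cohort data frame in the standard schema ([cohort_columns()]); in
#'   linked mode the latent generation targets (fat-free mass, phase angle)
#'   are attached as attribute `"latent"` for consistency checking.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  cols <- cohort_columns()
  if (n == 0L) {
    out <- data.frame(athlete_id = character(0), age = numeric(0),
                      weight_kg = numeric(0), stature_cm = numeric(0),
                      triceps_mm = numeric(0), subscapular_mm = numeric(0),
                      supraspinal_mm = numeric(0), medial_calf_mm = numeric(0),
                      arm_girth_cm = numeric(0), calf_girth_cm = numeric(0),
                      humerus_cm = numeric(0), femur_cm = numeric(0),
                      resistance_ohm = numeric(0), reactance_ohm = numeric(0),
                      position = character(0))
    return(out[cols])
  }
  set.seed(spec$seed)
  sigma <- diag(spec$sds) %*% spec$correlation %*% diag(spec$sds)
  dimnames(sigma) <- list(GEN_VARS, GEN_VARS)
  draws <- matrix(numeric(0), ncol = length(GEN_VARS),
                  dimnames = list(NULL, GEN_VARS))
  guard <- 0L
  while (nrow(draws) < n) {
    m <- max(2L * (n - nrow(draws)), 50L)
    z <- MASS::mvrnorm(m, mu = spec$means, Sigma = sigma)
    z <- matrix(z, ncol = length(GEN_VARS), dimnames = list(NULL, GEN_VARS))
    draws <- rbind(draws, z[valid_draws(z, spec$mode), , drop = FALSE])
    guard <- guard + 1L
    if (guard > 1000L) {
      stop("generate_cohort: rejection sampling failed to reach n; ",
           "check means/SDs against the physiological bounds", call. = FALSE)
    }
  }
  draws <- draws[seq_len(n), , drop = FALSE]
  r1 <- function(x) round(x, 1)  # instrument precision: 0.1 unit
  out <- data.frame(
    athlete_id = sprintf("ath%04d", seq_len(n)),
    age = r1(draws[, "age"]),
    weight_kg = r1(draws[, "weight_kg"]),
    stature_cm = r1(draws[, "stature_cm"]),
    triceps_mm = r1(draws[, "triceps_mm"]),
    subscapular_mm = r1(draws[, "subscapular_mm"]),
    supraspinal_mm = r1(draws[, "supraspinal_mm"]),
    medial_calf_mm = r1(draws[, "medial_calf_mm"]),
    arm_girth_cm = r1(draws[, "arm_girth_cm"]),
    calf_girth_cm = r1(draws[, "calf_girth_cm"]),
    humerus_cm = r1(draws[, "humerus_cm"]),
    femur_cm = r1(draws[, "femur_cm"]))
  if (spec$mode == "linked") {
    # back-solve from the rounded anthropometrics so the inversion is exact
    ffm_target <- draws[, "ffm_kg"]
    denom <- ffm_target + 2.261 - 0.525 * out$weight_kg - 5.462
    out$resistance_ohm <- 0.327 * out$stature_cm^2 / denom
    out$reactance_ohm <- out$resistance_ohm * draws[, "phase_angle"] * pi / 180
  } else {
    out$resistance_ohm <- r1(draws[, "resistance_ohm"])
    out$reactance_ohm <- r1(draws[, "reactance_ohm"])
  }
  # exact largest-remainder position allocation, then a seeded shuffle
  exact <- spec$position_mix * n
  counts <- floor(exact)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(exact - counts, names(exact), decreasing = c(TRUE, FALSE),
                 method = "radix")
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  out$position <- sample(rep(names(counts), counts))
  out <- out[cols]
  if (spec$mode == "linked") {
    # latent generation targets, exposed for consistency checks
    attr(out, "latent") <- data.frame(ffm_kg = draws[, "ffm_kg"],
                                      phase_angle = draws[, "phase_angle"])
  }
  out
}

#' Generate a study-shaped pair of cohorts (development n = 117, validation n = 59)
#'
#' One call reproduces the reference study shape end-to-end: a linked-mode
#' cohort of 176 athletes with the default specification, stratified-split by
#' playing position at a validation fraction of 1/3.
#'
#' @param seed integer seed driving both generation and the split.
#' @return list with `development` (117 rows) and `validation` (59 rows).
#' @export
make_study_cohorts <- function(seed = 1) {
  cohort <- generate_cohort(cohort_spec(n = 176, mode = "linked", seed = seed))
  stratified_split(cohort, fraction_validation = 1 / 3, strata = "position",
                   seed = seed)
}
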
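test_that("stratified split reproduces the study shape and is deterministic", {
  cohort <- linked_cohort(176, 21)
  sp <- stratified_split(cohort, 1 / 3, seed = 4)
  expect_identical(nrow(sp$development), 117L)
  expect_identical(nrow(sp$validation), 59L)
  # union = input, intersection empty
  expect_setequal(c(sp$development$athlete_id, sp$validation$athlete_id),
                  cohort$athlete_id)
  expect_length(intersect(sp$development$athlete_id,
                          sp$validation$athlete_id), 0)
  # per-stratum counts within one of exact proportionality
  for (pos in unique(cohort$position)) {
    n_pos <- sum(cohort$position == pos)
    got <- sum(sp$validation$position == pos)
    expect_lt(abs(got - n_pos * 59 / 176), 1)
  }
  sp2 <- stratified_split(cohort, 1 / 3, seed = 4)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(cohort, 1 / 3, seed = 5)
  expect_false(identical(sp$validation$athlete_id, sp3$validation$athlete_id))
})

test_that("stratified split rejects degenerate fractions and handles singletons", {
  cohort <- linked_cohort(30, 23)
  expect_error(stratified_split(cohort, 0, seed = 1), "between 0 and 1")
  expect_error(stratified_split(cohort, 1, seed = 1), "between 0 and 1")
  # 1 goalkeeper + 3 defenders at fraction 0.75: largest-remainder allocation
  # hands the goalkeeper stratum one validation slot, which the singleton rule
  # must refuse
  single <- do.call(rbind, lapply(1:4, function(i) valid_row(paste0("a", i))))
  single$position <- c("goalkeeper", "defender", "defender", "defender")
  expect_warning(sp <- stratified_split(single, 0.75, seed = 2),
                 "single member")
  expect_true("a1" %in% sp$development$athlete_id)
})

test_that("stepwise recovers an exact relationship and honours thresholds", {
  set.seed(61)
  d <- as.data.frame(matrix(rnorm(80 * 6), 80,
                            dimnames = list(NULL, paste0("x", 1:6))))
  d$y <- d$x3
  m <- stepwise_ols(d, "y")
  expect_identical(m$predictors, "x3")
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(m$see, 0, tolerance = 1e-9)
  expect_equal(unname(m$vif), 1)  # single-predictor convention
})

test_that("stepwise recovers coefficients on an identifiable design", {
  # well-conditioned candidates: the generating predictors are not spanned by
  # the decoys, so the selected set is identifiable
  set.seed(62)
  n <- 117
  d <- as.data.frame(matrix(rnorm(n * 8), n,
                            dimnames = list(NULL, paste0("x", 1:8))))
  truth <- c(x1 = 0.5, x2 = -0.3, x3 = 0.2)
  d$y <- 1.5 + as.matrix(d[names(truth)]) %*% truth + rnorm(n, 0, 0.16)
  m <- stepwise_ols(d, "y", paste0("x", 1:8))
  expect_true(all(names(truth) %in% m$predictors))
  sm <- summary(m$fit)$coefficients
  for (nm in names(truth)) {
    expect_lt(abs(sm[nm, "Estimate"] - truth[nm]), 2 * sm[nm, "Std. Error"])
  }
  # no retained predictor has partial p above the removal threshold
  for (j in m$predictors) {
    red <- stats::lm(stats::reformulate(setdiff(m$predictors, j), "y"), d)
    p <- anova(red, m$fit)$`Pr(>F)`[2]
    expect_lte(p, 0.10)
  }
})

test_that("stepwise falls back to the intercept-only model and skips collinear candidates", {
  d <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  d$y <- rep(2, 30)  # zero-variance response: nothing can enter
  expect_warning(m <- stepwise_ols(d, "y"), "intercept-only")
  expect_length(m$predictors, 0)
  expect_equal(unname(m$coefficients["(Intercept)"]), 2)

  set.seed(63)
  d2 <- data.frame(x1 = rnorm(50))
  d2$x2 <- 2 * d2$x1            # exact duplicate direction
  d2$y <- d2$x1 + rnorm(50, 0, 0.1)
  expect_warning(m2 <- stepwise_ols(d2, "y"), "collinear")
  expect_identical(m2$predictors, "x1")
})

test_that("stepwise rejects equal entry/removal thresholds", {
  d <- data.frame(x = rnorm(20), y = rnorm(20))
  expect_error(stepwise_ols(d, "y", p_enter = 0.1, p_remove = 0.1), "cycling")
})

test_that("under a pure-noise response, selection triggers at the family-wise rate", {
  # brute-force oracle: a non-empty model is returned exactly when the
  # smallest single-predictor partial p on the same draw is <= p_enter, and
  # over replicates that happens at roughly 1 - (1 - alpha)^k for k
  # near-independent candidates
  set.seed(77)
  k <- 6; n <- 50; reps <- 400
  nonempty <- oracle_hit <- logical(reps)
  for (i in seq_len(reps)) {
    d <- as.data.frame(matrix(rnorm(n * k), n,
                              dimnames = list(NULL, paste0("x", 1:k))))
    d$y <- rnorm(n)  # independent of every candidate
    m <- suppressWarnings(stepwise_ols(d, "y", paste0("x", 1:k)))
    nonempty[i] <- length(m$predictors) > 0
    pmin_ <- min(vapply(paste0("x", 1:k), function(j)
      summary(lm(reformulate(j, "y"), d))$coefficients[j, 4], numeric(1)))
    oracle_hit[i] <- pmin_ <= 0.05
  }
  expect_identical(nonempty, oracle_hit)
  expect_lt(abs(mean(nonempty) - (1 - 0.95^k)), 0.07)
})

test_that("fitted models satisfy the OLS identities", {
  cohort <- linked_cohort(117, 25)
  ref <- somatotype_reference(cohort)
  d <- cbind(candidate_set(cohort), endomorphy = ref$endomorphy)
  m <- suppressWarnings(stepwise_ols(d, "endomorphy",
                                     candidates = names(candidate_set(cohort))))
  # fitted-mean identity: mean(fitted) = mean(observed)
  expect_equal(mean(fitted(m$fit)), mean(d$endomorphy), tolerance = 1e-10)
  # reported R equals sqrt(R^2)
  expect_equal(m$r^2, m$r_squared, tolerance = 1e-12)
  expect_true(all(m$vif >= 1))
  expect_gte(m$see, 0)
})

test_that("VIF matches its closed forms and the independent car implementation", {
  # orthogonal columns -> all VIF 1
  q <- qr.Q(qr(matrix(rnorm(200 * 3), 200)))
  d <- as.data.frame(q); names(d) <- c("a", "b", "c")
  v <- vif(d, c("a", "b", "c"))
  # columns are mutually orthogonal but not exactly orthogonal to the
  # intercept, so VIFs sit within rounding of 1
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-3, ignore_attr = TRUE)
  expect_false(any(attr(v, "flagged")))

  # duplicated column -> infinite, flagged
  d$dup <- d$a
  v2 <- vif(d, c("a", "dup", "b"))
  expect_identical(unname(v2[c("a", "dup")]), c(Inf, Inf))
  expect_true(all(attr(v2, "flagged")[c("a", "dup")]))

  # bivariate closed form: r = 0.9 -> VIF ~ 1/(1 - 0.81) = 5.26, flagged
  set.seed(71)
  n <- 20000
  x1 <- rnorm(n); x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  v3 <- vif(data.frame(x1 = x1, x2 = x2), c("x1", "x2"))
  expect_equal(unname(v3["x1"]), 1 / (1 - 0.81), tolerance = 0.05)
  expect_true(all(attr(v3, "flagged")))

  skip_if_not_installed("car")
  cohort <- linked_cohort(117, 25)
  d4 <- cbind(candidate_set(cohort),
              endomorphy = somatotype_reference(cohort)$endomorphy)
  preds <- c("fm_percent", "triceps_mm", "supraspinal_mm", "stature_cm")
  fit <- lm(reformulate(preds, "endomorphy"), d4)
  expect_equal(as.numeric(vif(d4, preds)), as.numeric(car::vif(fit)),
               tolerance = 1e-6)
})

test_that("residual diagnostics detect what they should", {
  # Gaussian noise: normality not rejected in >= 90% of seeded replicates
  not_rejected <- 0L
  for (s in 1:100) {
    set.seed(s)
    d <- data.frame(x = rnorm(100))
    d$y <- 2 + d$x + rnorm(100, 0, 0.5)
    m <- stepwise_ols(d, "y", "x")
    dg <- fit_diagnostics(m)
    if (dg$ks_p > 0.05) not_rejected <- not_rejected + 1L
    expect_lt(abs(dg$residual_mean), 1e-10)
  }
  expect_gte(not_rejected, 90L)

  # heavy-tailed noise: rejected in the majority of replicates
  rejected <- 0L
  for (s in 1:40) {
    set.seed(s)
    d <- data.frame(x = rnorm(150))
    d$y <- 2 + d$x + 0.5 * rt(150, df = 1.5)
    m <- stepwise_ols(d, "y", "x")
    if (fit_diagnostics(m)$ks_p < 0.05) rejected <- rejected + 1L
  }
  expect_gt(rejected, 20L)

  # exact fit: degenerate, reported without crashing
  d <- data.frame(x = 1:20 / 3)
  d$y <- 2 * d$x
  m <- stepwise_ols(d, "y", "x")
  dg <- fit_diagnostics(m)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$ks_p))
})

test_that("the candidate table matches the development variable list", {
  cohort <- linked_cohort(15, 27)
  cand <- candidate_set(cohort)
  expect_setequal(names(cand),
                  c("age", "resistance_ohm", "reactance_ohm", "phase_angle",
                    "ffm_kg", "fm_kg", "fm_percent", "ffm_stature",
                    "stature_cm", "weight_kg", "bmi", "triceps_mm",
                    "subscapular_mm", "supraspinal_mm", "medial_calf_mm",
                    "arm_girth_cm", "calf_girth_cm", "s2_resistance",
                    "s2_reactance"))
  # derived columns are recomputed from raw measurements
  expect_equal(cand$bmi, body_mass_index(cohort$weight_kg, cohort$stature_cm))
  expect_equal(cand$ffm_stature, cand$ffm_kg / cohort$stature_cm)
})
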
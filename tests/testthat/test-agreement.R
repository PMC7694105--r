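test_that("pure error matches hand arithmetic and its limiting cases", {
  expect_equal(pure_error(c(2.1, 2.9), c(2.0, 3.0)), 0.1, tolerance = 1e-12)
  x <- c(1.2, 2.4, 3.1, 4.8)
  expect_equal(pure_error(x, x), 0)
  expect_equal(pure_error(x + 0.37, x), 0.37, tolerance = 1e-12)
  expect_equal(pure_error(x - 0.37, x), 0.37, tolerance = 1e-12)
  expect_error(pure_error(numeric(0), numeric(0)), "n >= 1")
})

test_that("pure error decomposes into bias and scatter", {
  set.seed(81)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    p <- rnorm(n, 3, 1); o <- rnorm(n, 3, 1)
    d <- p - o
    expect_equal(pure_error(p, o)^2,
                 mean(d)^2 + (n - 1) / n * sd(d)^2, tolerance = 1e-12)
  }
})

test_that("Lin's CCC matches closed forms and its decomposition identity", {
  self <- lin_ccc(c(1, 2, 3, 5), c(1, 2, 3, 5))
  expect_equal(self, list(ccc = 1, rho = 1, c_b = 1))
  shift <- lin_ccc(c(1, 2, 3), c(2, 3, 4))
  expect_equal(shift$ccc, 4 / 7, tolerance = 1e-12)
  expect_equal(shift$rho, 1)
  expect_equal(shift$c_b, 4 / 7, tolerance = 1e-12)
  # published cross-validation decomposition: rho * C_b recovers CCC at 2 d.p.
  expect_equal(round_half_up(0.8957 * 0.9917, 2), 0.89)
  expect_equal(round_half_up(0.9346 * 0.9973, 2), 0.93)
  expect_error(lin_ccc(rep(1, 5), 1:5), "zero-variance")
  expect_error(lin_ccc(1:2, 1:2), "n >= 3")
})

test_that("CCC is symmetric, bounded, and never beats the Pearson correlation", {
  set.seed(82)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    x <- rnorm(n, 2, 1)
    y <- 0.5 * x + rnorm(n, sample(c(0, 1), 1), 0.5)
    a <- lin_ccc(x, y); b <- lin_ccc(y, x)
    expect_equal(a$ccc, b$ccc, tolerance = 1e-12)
    expect_true(a$ccc >= -1 && a$ccc <= 1)
    expect_lte(abs(a$ccc), abs(a$rho) + 1e-12)
    expect_equal(a$ccc, a$rho * a$c_b, tolerance = 1e-12)
  }
  # equal means and variances: CCC reduces to the Pearson correlation
  set.seed(83)
  x <- rnorm(2000)
  y <- x[sample(2000)]  # same marginal, permuted
  cc <- lin_ccc(x, y)
  expect_equal(cc$ccc, cc$rho, tolerance = 1e-10)
})

test_that("the n-1 CCC variant differs as expected at small n", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  n_form <- lin_ccc(x, y)$ccc
  n1_form <- lin_ccc(x, y, denominator = "n-1")$ccc
  # closed forms: 2*cov/(2*var + 1) with cov = var = 2/3 (n) or 1 (n-1)
  expect_equal(n_form, (4 / 3) / (7 / 3), tolerance = 1e-12)
  expect_equal(n1_form, 2 / 3, tolerance = 1e-12)
})

test_that("Bland-Altman statistics follow their definitions", {
  x <- c(1.3, 2.8, 4.1, 5.9)
  ident <- bland_altman(x, x)
  expect_equal(ident[c("bias", "loa_low", "loa_high")],
               list(bias = 0, loa_low = 0, loa_high = 0))
  expect_true(is.na(ident$trend_r))  # undefined trend reported as n/a

  ba <- bland_altman(c(10, 20, 30) + c(-0.2, 0, 0.2), c(10, 20, 30))
  expect_equal(ba$bias, 0, tolerance = 1e-12)
  expect_equal(ba$loa_low, -0.392, tolerance = 1e-12)
  expect_equal(ba$loa_high, 0.392, tolerance = 1e-12)

  # sign convention: predictions running uniformly 0.15 below the reference
  ref <- c(2.1, 2.6, 3.4, 1.8)
  ba2 <- bland_altman(ref - 0.15, ref)
  expect_equal(ba2$bias, -0.15, tolerance = 1e-12)
})

test_that("95% limits of agreement cover ~95% of large Gaussian samples", {
  set.seed(84)
  ref <- rnorm(10000, 3, 0.6)
  pred <- ref + rnorm(10000, -0.05, 0.2)
  ba <- bland_altman(pred, ref)
  d <- pred - ref
  coverage <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_lt(abs(coverage - 0.95), 0.01)
})

test_that("cross-validation reports all agreement statistics per component", {
  cohort <- linked_cohort(59, 31)
  rep_ <- cross_validate(cohort)
  expect_s3_class(rep_, "agreement_report")
  expect_identical(rep_$component, c("endomorphy", "mesomorphy", "ectomorphy"))
  expect_identical(attr(rep_, "direction"), "predicted - reference")
  # report invariants
  expect_true(all(rep_$loa_low <= rep_$bias & rep_$bias <= rep_$loa_high))
  expect_true(all(abs(rep_$ccc) <= abs(rep_$rho) + 1e-12))
  expect_true(all(rep_$c_b > 0 & rep_$c_b <= 1 + 1e-12))
  expect_true(all(rep_$r_squared >= 0 & rep_$r_squared <= 1))
  expect_output(print(rep_), "predicted - reference")
})

test_that("swapping predicted and reference flips bias but not concordance", {
  set.seed(85)
  a <- rnorm(40, 3, 0.5)
  b <- a + rnorm(40, -0.1, 0.2)
  expect_equal(lin_ccc(a, b)$ccc, lin_ccc(b, a)$ccc, tolerance = 1e-12)
  expect_equal(bland_altman(a, b)$bias, -bland_altman(b, a)$bias,
               tolerance = 1e-12)
})

test_that("cross-validation accepts freshly fitted models", {
  cohort <- linked_cohort(176, 33)
  sp <- stratified_split(cohort, 1 / 3, seed = 33)
  dev_ref <- somatotype_reference(sp$development)
  d <- cbind(candidate_set(sp$development),
             dev_ref[c("endomorphy", "mesomorphy", "ectomorphy")])
  models <- lapply(setNames(nm = c("endomorphy", "mesomorphy", "ectomorphy")),
                   function(resp) suppressWarnings(
                     stepwise_ols(d, resp,
                                  candidates = names(candidate_set(sp$development)))))
  rep_ <- cross_validate(sp$validation, models = models)
  expect_identical(attr(rep_, "source"), "fitted stepwise models")
  # the endomorphy and ectomorphy responses are fully determined by available
  # candidates, so their fitted models validate near-perfectly; mesomorphy
  # depends on bone breadths the candidate pool does not contain, so it is
  # merely strongly concordant
  expect_true(all(rep_$ccc[rep_$component != "mesomorphy"] > 0.95))
  expect_gt(rep_$ccc[rep_$component == "mesomorphy"], 0.8)
  expect_true(all(rep_$pure_error < 0.6))
})
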
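# Independent brute-force evaluations of the three component formulas,
# coded separately from the package implementation (Horner form, explicit
# branch-by-branch loop) so the two routes can disagree.
oracle_endo <- function(tri, sub, sup, st) {
  x <- (tri + sub + sup) * (170.18 / st)
  val <- -0.7182 + x * (0.1451 + x * (-0.00068 + x * 0.0000014))
  max(val, 0.1)
}
oracle_meso <- function(hb, fb, cag, tri, cg, mcf, st) {
  terms <- c(0.858 * hb, 0.601 * fb, 0.188 * (cag - tri * 0.1),
             0.161 * (cg - mcf * 0.1), -0.131 * st, 4.5)
  max(sum(terms), 0.1)
}
oracle_ecto <- function(st, wt) {
  hwr <- st / exp(log(wt) / 3)
  if (hwr >= 40.75) return(max(0.732 * hwr - 28.58, 0.1))
  if (hwr > 38.25) return(max(0.463 * hwr - 17.63, 0.1))
  0.1
}

test_that("component ratings reproduce the printed group means and hand evaluations", {
  expect_equal(round_half_up(endomorphy_reference(6.1, 9.5, 6.7, 183.8)), 2.0)
  expect_equal(round_half_up(mesomorphy_reference(7.2, 10.2, 33.1, 6.1,
                                                  37.9, 5.4, 183.8)), 4.9)
  expect_equal(round_half_up(ectomorphy_reference(183.8, 79.5)), 2.7)
  # hand evaluations of the closed forms
  expect_equal(endomorphy_reference(10, 12, 8, 170.18), 3.0606, tolerance = 1e-4)
  expect_equal(mesomorphy_reference(7.0, 9.5, 30.0, 10.0, 36.0, 6.0, 175.0),
               4.4419, tolerance = 1e-4)
  expect_equal(ectomorphy_reference(175, 87), 0.6557, tolerance = 1e-3)
})

test_that("each component agrees with its brute-force oracle on random valid inputs", {
  r <- runif_mat(1000, list(tri = c(3, 25), sub = c(4, 30), sup = c(3, 25),
                            mcf = c(3, 20), cag = c(24, 42), cg = c(30, 45),
                            hb = c(5.5, 8.5), fb = c(8, 12),
                            st = c(150, 210), wt = c(50, 110)), seed = 101)
  endo <- endomorphy_reference(r$tri, r$sub, r$sup, r$st)
  meso <- mesomorphy_reference(r$hb, r$fb, r$cag, r$tri, r$cg, r$mcf, r$st)
  ecto <- ectomorphy_reference(r$st, r$wt)
  for (i in seq_len(nrow(r))) {
    expect_equal(endo[i], oracle_endo(r$tri[i], r$sub[i], r$sup[i], r$st[i]),
                 tolerance = 1e-9)
    expect_equal(meso[i], oracle_meso(r$hb[i], r$fb[i], r$cag[i], r$tri[i],
                                      r$cg[i], r$mcf[i], r$st[i]),
                 tolerance = 1e-9)
    expect_equal(ecto[i], oracle_ecto(r$st[i], r$wt[i]), tolerance = 1e-9)
  }
  # floor: no rating below 0.1 anywhere in the valid range
  expect_true(all(c(endo, meso, ecto) >= 0.1))
})

test_that("floors engage in the degenerate limits", {
  expect_equal(endomorphy_reference(1e-6, 1e-6, 1e-6, 180), 0.1)
  expect_equal(ectomorphy_reference(170, 90), 0.1)   # HWR ~ 37.9, floor branch
  # mesomorphy approaches its 4.5 intercept as the size terms vanish
  expect_equal(mesomorphy_reference(1e-9, 1e-9, 1e-6, 1e-7, 1e-6, 1e-7, 1e-9),
               4.5, tolerance = 1e-5)
})

test_that("component monotonicities hold", {
  base <- endomorphy_reference(6, 9, 6, 180)
  expect_gt(endomorphy_reference(7, 9, 6, 180), base)
  expect_gt(endomorphy_reference(6, 10, 6, 180), base)
  expect_gt(endomorphy_reference(6, 9, 7, 180), base)
  expect_lt(mesomorphy_reference(7, 10, 33, 6, 38, 5, 190),
            mesomorphy_reference(7, 10, 33, 6, 38, 5, 180))
  expect_gte(ectomorphy_reference(190, 80), ectomorphy_reference(180, 80))
})

test_that("classification covers the rating space with exactly one of 13 labels", {
  labels13 <- c("central",
                "balanced endomorph", "balanced mesomorph", "balanced ectomorph",
                "mesomorphic endomorph", "ectomorphic endomorph",
                "endomorphic mesomorph", "ectomorphic mesomorph",
                "endomorphic ectomorph", "mesomorphic ectomorph",
                "endomorph-mesomorph", "mesomorph-ectomorph",
                "endomorph-ectomorph")
  expect_identical(classify_somatotype(2.0, 4.9, 2.7), "ectomorphic mesomorph")
  expect_identical(classify_somatotype(3, 3, 3), "central")
  expect_identical(classify_somatotype(5, 2, 2), "balanced endomorph")
  # grid including exact 0.5 boundaries
  g <- expand.grid(e = seq(0.5, 7, by = 0.5), m = seq(0.5, 7, by = 0.5),
                   c = seq(0.5, 7, by = 0.5))
  lab <- classify_somatotype(g$e, g$m, g$c)
  expect_false(any(is.na(lab)))
  expect_true(all(lab %in% labels13))
  # ties fall toward the balanced/hybrid labels, never a dominant form
  expect_identical(classify_somatotype(4.0, 4.5, 2.0), "endomorph-mesomorph")
  expect_identical(classify_somatotype(2.0, 4.5, 4.0), "mesomorph-ectomorph")
})

test_that("somatochart projection satisfies its defining identities", {
  expect_equal(somatochart_point(2.0, 4.9, 2.7), data.frame(x = 0.7, y = 5.1))
  expect_equal(somatochart_point(3, 3, 3), data.frame(x = 0, y = 0))
  expect_equal(somatochart_point(1, 7, 1), data.frame(x = 0, y = 12))
})

test_that("cohort-level reference somatotype appends components and handles n = 0", {
  cohort <- linked_cohort(30, 7)
  ref <- somatotype_reference(cohort)
  expect_true(all(c("endomorphy", "mesomorphy", "ectomorphy", "category",
                    "chart_x", "chart_y") %in% names(ref)))
  expect_equal(ref$endomorphy,
               endomorphy_reference(cohort$triceps_mm, cohort$subscapular_mm,
                                    cohort$supraspinal_mm, cohort$stature_cm))
  empty <- somatotype_reference(generate_cohort(cohort_spec(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("measurement-error propagation returns a per-athlete spread", {
  cohort <- linked_cohort(5, 13)
  mc <- somatotype_measurement_error(cohort, n_replicates = 30, seed = 2)
  expect_identical(nrow(mc), 5L)
  expect_true(all(mc$endomorphy_sd > 0))
  mc2 <- somatotype_measurement_error(cohort, n_replicates = 30, seed = 2)
  expect_equal(mc, mc2)
})
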
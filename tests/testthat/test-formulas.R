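test_that("Haigis-L corneal power reproduces the regression line", {
  expect_equal(corneal_power_haigis_l(8.79), 32.57643, tolerance = 1e-5)
  expect_equal(corneal_power_haigis_l(8.00), 37.0103, tolerance = 1e-4)
  # at the root of the linear term only the -0.35 offset remains
  expect_equal(corneal_power_haigis_l(82.2603 / 5.6125), -0.35,
               tolerance = 1e-9)
})

test_that("the SA regression line evaluates and roots where it should", {
  expect_equal(pe_from_sa(0), -2.3488)
  expect_equal(pe_from_sa(sa8_at_root()), 0, tolerance = 1e-12)
  expect_equal(sa8_at_root(), 4.02881, tolerance = 1e-5)
  expect_equal(pe_from_sa(3.69), -0.19753, tolerance = 1e-5)
  m <- pe_model(1, -2)
  expect_equal(pe_from_sa(2, m), 0)
})

test_that("SA-corrected corneal power shifts Haigis-L by the corneal-plane error", {
  # zero predicted error leaves the Haigis-L power unchanged
  expect_equal(corneal_power_modified(8.79, sa8_at_root()),
               corneal_power_haigis_l(8.79), tolerance = 1e-12)
  expect_equal(corneal_power_modified(8.79, 3.69), 32.77349,
               tolerance = 1e-5)
  expect_equal(corneal_power_modified(8.79, 0), 34.86085, tolerance = 1e-5)
  # a zero model collapses the correction exactly
  expect_identical(corneal_power_modified(8.4, 3.1, model = pe_model(0, 0)),
                   corneal_power_haigis_l(8.4))
  # positive predicted error lowers Z', raising the computed power
  expect_lt(corneal_power_modified(8.79, 5), corneal_power_haigis_l(8.79))
  expect_gt(iol_power_for_target(28.43, 6.59413,
                                 corneal_power_modified(8.79, 5)),
            iol_power_for_target(28.43, 6.59413,
                                 corneal_power_haigis_l(8.79)))
})

test_that("per-eye prediction chains the optics worked example", {
  res <- predict_eye(28.43, 3.62, 8.79, implanted_power = 20,
                     postop_se = 1.418, formula = "haigis-l")
  expect_equal(res$elp, 6.59413, tolerance = 1e-5)
  expect_equal(res$corneal_power, 32.57643, tolerance = 1e-5)
  expect_equal(res$iol_power, 22.366, tolerance = 1e-3)
  expect_equal(res$predicted_se, 1.618, tolerance = 1e-3)
  expect_equal(res$pe, -0.200, tolerance = 1e-3)

  # implanting the formula's own emmetropic power predicts plano
  res0 <- predict_eye(28.43, 3.62, 8.79, implanted_power = res$iol_power,
                      formula = "haigis-l")
  expect_equal(res0$predicted_se, 0, tolerance = 1e-12)
})

test_that("modified-minus-Haigis-L prediction shift tracks the expected error", {
  grid <- expand.grid(al = c(24.5, 28.43, 33), acd = c(2.8, 3.62, 4.5),
                      r = c(7.9, 8.79, 10.1), sa8 = c(1.2, 3.69, 4.5, 5.4))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- iol_power_for_target(g$al, elp_haigis(g$acd, g$al),
                              corneal_power_haigis_l(g$r))
    hl <- predict_eye(g$al, g$acd, g$r, implanted_power = p,
                      formula = "haigis-l")$predicted_se
    mod <- predict_eye(g$al, g$acd, g$r, sa8 = g$sa8, implanted_power = p,
                       formula = "modified-haigis-l")$predicted_se
    expect_equal(sign(mod - hl), sign(pe_from_sa(g$sa8)))
  }
})

test_that("all three formulas agree on the constructed agreement fixture", {
  r <- 8.79
  idx <- matching_kerat_index(r)
  sa <- sa8_at_root()
  powers <- vapply(c("haigis", "haigis-l", "modified-haigis-l"),
                   function(fm) predict_eye(28.43, 3.62, r, sa8 = sa,
                                            formula = fm,
                                            keratometric_index = idx)$iol_power,
                   0)
  expect_equal(unname(diff(range(powers))), 0, tolerance = 1e-9)
})

test_that("cohort prediction validates required measurements per formula", {
  cohort <- toy_cohort()
  scored <- predict_cohort(cohort, "haigis-l")
  expect_equal(scored$pe_d[1], -0.200, tolerance = 1e-3)
  expect_identical(attr(scored, "formula"), "haigis-l")

  no_sa <- cohort[setdiff(names(cohort), "sa8_um")]
  expect_error(predict_cohort(no_sa, "modified-haigis-l"), "sa8_um")
  expect_silent(predict_cohort(no_sa, "haigis-l"))

  cohort$sa8_um[2] <- NA
  expect_error(predict_cohort(cohort, "modified-haigis-l"), "toy_2")

  empty <- predict_cohort(cohort[0, ], "haigis-l")
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("predicted_se_d", "pe_d") %in% names(empty)))
})
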
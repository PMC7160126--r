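test_that("Pearson correlation matches the explicit-sum oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, x)$r, 1.0)
  expect_equal(pearson_cor(x, 2 * x)$r, 1.0)
  expect_equal(pearson_cor(x, -x)$r, -1.0)
  res <- pearson_cor(x, c(2, 2, 4, 4))
  expect_equal(res$r, 0.89443, tolerance = 1e-5)
  oracle <- pearson_oracle(x, c(2, 2, 4, 4))
  expect_equal(res$r, oracle$r, tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- pearson_cor(a, b)
    want <- pearson_oracle(a, b)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("degenerate or malformed series are rejected", {
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(pearson_cor(c(1, 2, 3), c(5, 5, 5)), "degenerate")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
  expect_error(pearson_cor(1:4, 1:3), "equal length")
  expect_error(fit_pe_regression(rep(2, 5), rnorm(5)), "degenerate")
  expect_error(fit_pe_regression(1:2, 1:2), "at least 3")
})

test_that("the PE regression equals the normal-equations oracle", {
  # exact interpolation of a line
  fit <- fit_pe_regression(c(0, 1, 2, 5), 2 * c(0, 1, 2, 5) - 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, -1)
  expect_equal(fit$r, 1)

  fit2 <- fit_pe_regression(c(1, 2, 3, 4), c(2, 2, 4, 4))
  expect_equal(fit2$slope, 0.8, tolerance = 1e-12)
  expect_equal(fit2$intercept, 1.0, tolerance = 1e-12)

  set.seed(23)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    sa <- rnorm(n, 3.7, 0.9); pe <- rnorm(n)
    got <- fit_pe_regression(sa, pe)
    want <- ols_oracle(sa, pe)
    expect_equal(got$slope, want$slope, tolerance = 1e-9)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-9)
    # an OLS line passes through the centroid
    expect_equal(got$slope * mean(sa) + got$intercept, mean(pe),
                 tolerance = 1e-9)
  }
})

test_that("slope, intercept and r transform correctly under affine PE rescaling", {
  set.seed(5)
  sa <- rnorm(40, 3.7, 0.9)
  pe <- 0.6 * sa - 2.4 + rnorm(40, 0, 0.4)
  base <- fit_pe_regression(sa, pe)
  for (ab in list(c(2, 0.5), c(-1.5, 3), c(0.1, -4))) {
    scaled <- fit_pe_regression(sa, ab[1] * pe + ab[2])
    expect_equal(scaled$slope, ab[1] * base$slope, tolerance = 1e-9)
    expect_equal(scaled$intercept, ab[1] * base$intercept + ab[2],
                 tolerance = 1e-9)
    expect_equal(abs(scaled$r), abs(base$r), tolerance = 1e-12)
  }
})

test_that("predictor screening ranks by |r| and flags degenerate columns", {
  cohort <- generate_cohort(training_cohort_params(seed = 9))
  scored <- predict_cohort(cohort, "haigis-l")
  tab <- correlate_predictors(scored)
  expect_identical(tab$predictor[1], "SA8")
  expect_true(all(diff(abs(tab$r[!tab$degenerate])) <= 1e-12))

  # a predictor column duplicated from PE ranks first with r = 1
  scored$q6 <- scored$pe_d
  tab2 <- correlate_predictors(scored)
  expect_identical(tab2$predictor[1], "Q6")
  expect_equal(tab2$r[1], 1.0, tolerance = 1e-12)

  # an all-constant predictor is flagged, not fatal
  scored$q8 <- 1.0
  tab3 <- correlate_predictors(scored)
  expect_true(tab3$degenerate[tab3$predictor == "Q8"])
  expect_true(all(!tab3$degenerate[tab3$predictor != "Q8"]))

  expect_error(correlate_predictors(cohort), "pe_d")
  expect_error(correlate_predictors(scored, predictors = "AL2"), "unknown")
})

test_that("calibration recovers a noiseless generator exactly", {
  params <- training_cohort_params(seed = 31)
  params$pe_model <- pe_model(0.42, -1.7)
  params$residual_sd <- 0
  fit <- sa_calibrate(generate_cohort(params))
  expect_equal(fit$model$slope, 0.42, tolerance = 1e-9)
  expect_equal(fit$model$intercept, -1.7, tolerance = 1e-9)
  expect_equal(fit$fit$r, 1, tolerance = 1e-9)
})

test_that("calibration refuses cohorts that cannot identify the line", {
  cohort <- generate_cohort(training_cohort_params(seed = 2, n = 2))
  expect_error(sa_calibrate(cohort), "at least 3")
  c3 <- generate_cohort(training_cohort_params(seed = 2, n = 10))
  c3$postop_se_d[4] <- NA
  expect_error(sa_calibrate(c3), "postop_se_d")
})

test_that("calibration recovers the generating line over seeded replicates", {
  slopes <- numeric(200)
  intercepts <- numeric(200)
  for (k in 1:200) {
    cohort <- generate_cohort(training_cohort_params(seed = 5000 + k,
                                                     truncate_sa8 = FALSE))
    fit <- sa_calibrate(cohort)
    slopes[k] <- fit$model$slope
    intercepts[k] <- fit$model$intercept
  }
  expect_lt(abs(mean(slopes) - 0.583), 0.02)
  expect_lt(abs(mean(intercepts) - (-2.3488)), 0.08)
})

test_that("the fitted object supports the standard modelling methods", {
  cohort <- generate_cohort(training_cohort_params(seed = 77))
  fit <- sa_calibrate(cohort)
  expect_s3_class(fit, "sa_fit")
  co <- coef(fit)
  expect_named(co, c("intercept", "slope"))
  expect_equal(unname(co["slope"]), fit$fit$slope)

  # predict on SA values is the fitted line
  expect_equal(predict(fit, c(2, 4)),
               co["slope"] * c(2, 4) + co["intercept"],
               ignore_attr = TRUE)
  # predict on a cohort scores it under the fitted modified formula
  scored <- predict(fit, cohort)
  expect_identical(attr(scored, "formula"), "modified-haigis-l")
  # residuals are data minus line, and average to zero (OLS with intercept)
  expect_equal(mean(residuals(fit)), 0, tolerance = 1e-10)
  expect_equal(fitted(fit) + residuals(fit), fit$data$pe, tolerance = 1e-12)

  sm <- summary(fit)
  expect_s3_class(sm, "summary.sa_fit")
  expect_equal(sm$residual_sd, sd(residuals(fit)))

  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]], sims[[2]]))
  expect_identical(simulate(fit, nsim = 1, seed = 4)[[1]], sims[[1]])
})
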
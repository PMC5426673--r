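test_that("fit_ols agrees with an independent normal-equation oracle", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 5))
    y <- runif(1, -3, 3) + runif(1, -5, 5) * x + rnorm(n, sd = runif(1, 0.1, 4))
    fit <- fit_ols(x, y)
    oracle <- ols_oracle(x, y)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$rss, oracle$rss, tolerance = 1e-8)
    expect_equal(fit$see, oracle$see, tolerance = 1e-8)
  }
})

test_that("exact small cases and degenerate designs behave as specified", {
  fit <- fit_ols(1:5, c(2, 4, 6, 8, 10))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$see, 0)        # perfect fit: zero prediction error
  expect_equal(fit$adj_r2, 1)
  expect_true(is.na(fit$aic))
  expect_error(compute_aic(fit), class = "adipocut_degenerate_error")

  expect_error(fit_ols(rep(2, 6), rnorm(6)),
               class = "adipocut_degenerate_error")
  expect_error(fit_ols(1:3, 1:3), class = "adipocut_insufficient_data_error")
  expect_error(fit_ols(1:5, 1:4), class = "adipocut_input_error")
})

test_that("adjusted R2 never exceeds R2, with equality only at a perfect fit", {
  set.seed(32)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- x + rnorm(n, sd = runif(1, 0.01, 3))
    fit <- fit_ols(x, y)
    expect_lte(fit$adj_r2, fit$r2)
    if (fit$r2 < 1) expect_lt(fit$adj_r2, fit$r2)
  }
})

test_that("AIC differences follow n ln(RSS ratio) and ignore additive constants", {
  # two 41-subject fits with residual sums 697.7 and 849.3
  f1 <- regression_summary(1, 0, n = 41, see = sqrt(697.7 / 39))
  f2 <- regression_summary(1, 0, n = 41, see = sqrt(849.3 / 39))
  delta <- compute_aic(f2) - compute_aic(f1)
  expect_equal(delta, 41 * log(849.3 / 697.7), tolerance = 1e-9)
  expect_equal(delta, 8.06155406, tolerance = 1e-6)

  # equal rss and n give a zero difference; constants cancel in deltas
  expect_equal(compute_aic(f1) - compute_aic(f1), 0)
  expect_equal((compute_aic(f2) + 123.4) - (compute_aic(f1) + 123.4), delta)
})

test_that("rescaling the outcome shifts every candidate's AIC equally", {
  set.seed(33)
  n <- 25
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 2 + x1 + 0.3 * x2 + rnorm(n)
  d0 <- compute_aic(fit_ols(x2, y)) - compute_aic(fit_ols(x1, y))
  yc <- y * 7.3
  dc <- compute_aic(fit_ols(x2, yc)) - compute_aic(fit_ols(x1, yc))
  expect_equal(dc, d0, tolerance = 1e-9)
})

test_that("the SEE confidence factor matches its chi-squared definition", {
  expect_equal(round(see_ci_factor(39), 2), 1.25)
  # shorthand exp(1.96 / sqrt(2 df)) agrees to 2 dp at df = 39
  expect_equal(round(exp(1.96 / sqrt(2 * 39)), 2), round(see_ci_factor(39), 2))
  # strictly decreasing in df, tending to 1
  dfs <- c(5, 10, 20, 50, 100, 1000, 1e5)
  f <- see_ci_factor(dfs)
  expect_true(all(diff(f) < 0))
  expect_lt(f[length(f)], 1.01)
  expect_error(see_ci_factor(0), class = "adipocut_domain_error")
  # bounds bracket the SEE and compose into the factor
  b <- see_ci_bounds(4.1, 39)
  expect_lt(b$lower, 4.1); expect_gt(b$upper, 4.1)
  expect_equal(sqrt((b$upper / 4.1) * (4.1 / b$lower)), b$factor,
               tolerance = 1e-12)
})

test_that("geometric summaries follow the log-scale definition", {
  g <- geometric_summary(rep(exp(1), 3))
  expect_equal(g$geo_mean, exp(1))
  expect_equal(g$factor_sd, 1)
  g2 <- geometric_summary(c(1, exp(2)))
  expect_equal(g2$geo_mean, exp(1), tolerance = 1e-12)
  expect_equal(g2$factor_sd, exp(sqrt(2)), tolerance = 1e-12)
  # ln(geo mean) is exactly the mean of the logs
  set.seed(34)
  v <- exp(rnorm(40, 6, 1))
  expect_equal(log(geometric_summary(v)$geo_mean), mean(log(v)),
               tolerance = 1e-12)
  expect_error(geometric_summary(c(1, 0, 2)),
               class = "adipocut_domain_error")
})

test_that("undetectable-VAT exclusion removes exactly the zero records", {
  cohort <- tibble::tibble(id = as.character(1:40), vat_g = c(rep(0, 8), 1:32))
  ex <- exclude_undetectable_vat(cohort)
  expect_equal(nrow(ex$retained), 32)
  expect_equal(ex$n_excluded, 8)
  ex2 <- exclude_undetectable_vat(ex$retained)
  expect_equal(ex2$n_excluded, 0)
  expect_identical(ex2$retained, ex$retained)
})

test_that("fit_index_models fits every sex x predictor stratum consistently", {
  data <- simulate_cohort(small_config(), seed = 41) |> add_indices()
  fm <- fit_index_models(data, "fat_pct")
  expect_equal(nrow(fm), 10)
  expect_setequal(unique(fm$predictor), c("BMI", "WC", "WHR", "WHtR", "WHT.5R"))
  expect_true(all(fm$n[fm$sex == "M"] == 41))
  expect_true(all(fm$n_excluded == 0))

  lv <- fit_index_models(data, "log_vat")
  zeros_f <- sum(data$vat_g == 0 & data$sex == "F")
  expect_true(all(lv$n_excluded[lv$sex == "F"] == zeros_f))
  expect_true(all(lv$n[lv$sex == "F"] == 40 - zeros_f))
  # each row's stored fit reproduces the summary columns
  i <- which(lv$sex == "M" & lv$predictor == "WHtR")
  expect_equal(lv$slope[i], lv$fit[[i]]$slope)
  expect_equal(lv$aic[i], compute_aic(lv$fit[[i]]))
})
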
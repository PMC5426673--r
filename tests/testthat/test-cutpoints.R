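test_that("t quantiles match printed values and an integration oracle", {
  expect_equal(round(t_quantile(0.75, 39), 3), 0.681)
  expect_equal(t_quantile(0.5, 7), 0)
  expect_equal(t_quantile(0.5, 500), 0)
  # independent oracle: invert the integrated t density at p = 0.975
  dens <- function(t, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + t^2 / df)^(-(df + 1) / 2)
  }
  cdf <- function(q, df) {
    0.5 + stats::integrate(dens, 0, q, df = df, rel.tol = 1e-10)$value
  }
  oracle <- stats::uniroot(function(q) cdf(q, 200) - 0.975, c(0, 5),
                           tol = 1e-9)$root
  expect_equal(t_quantile(0.975, 200), oracle, tolerance = 1e-6)
  expect_equal(round(t_quantile(0.975, 10000), 3), 1.960)
  expect_error(t_quantile(1, 39), class = "adipocut_domain_error")
  expect_error(t_quantile(0.75, 0), class = "adipocut_domain_error")
})

test_that("the small-sample SEE adjustment reproduces the worked numbers", {
  expect_equal(round(inflate_see(4.1, 41), 1), 4.2)
  # the literal (non-root) factor gives 4.3 instead — kept as an option
  expect_equal(round(inflate_see(4.1, 41, method = "literal"), 1), 4.3)
  expect_equal(inflate_see(5.0, 50), 5.0 * sqrt(1 + 1 / 50 + 1 / 47))
  expect_equal(round(inflate_see(5.0, 50), 3), 5.102)
  expect_equal(inflate_see(3, 1e9), 3, tolerance = 1e-8)  # factor -> 1
  expect_gte(inflate_see(2.2, 12), 2.2)
  expect_error(inflate_see(4.1, 3), class = "adipocut_domain_error")
  expect_error(inflate_see(0, 41), class = "adipocut_domain_error")
})

test_that("the required predicted value inverts the t statistic", {
  expect_equal(round(required_predicted(25, 0.681, 4.2), 1), 27.9)
  expect_equal(required_predicted(40, 0, 5), 40)  # p = 0.5 case
  expect_equal(required_predicted(35, 0.681, 5.25), 38.57525)
  expect_error(required_predicted(25, 0.681, 0),
               class = "adipocut_domain_error")
})

test_that("inverting the prediction equation recovers the index value", {
  fit <- regression_summary(99.7, -24.7, n = 41, see = 4.1)
  expect_equal(round(invert_regression(fit, 27.9), 2), 0.53)
  ident <- regression_summary(1, 0, n = 41, see = 4.1)
  expect_equal(invert_regression(ident, 12.3), 12.3)
  f2 <- regression_summary(2, 10, n = 41, see = 4.1)
  expect_equal(invert_regression(f2, 20), 5)
  neg <- regression_summary(-3, 10, n = 41, see = 4.1)
  expect_error(invert_regression(neg, 20), class = "adipocut_domain_error")
})

test_that("the full chain reproduces the printed male derivation", {
  fit <- regression_summary(99.7, -24.7, n = 41, see = 4.1,
                            predictor = "WHtR", outcome = "fat_pct",
                            sex = "M")
  cp <- derive_cutpoint(fit, threshold = 25, paper_mode = TRUE)
  expect_equal(cp$t_value, 0.681)
  expect_equal(cp$see_adjusted, 4.2)
  expect_equal(cp$required_predicted, 27.9)
  expect_equal(round(cp$cutpoint, 2), 0.53)
  # full-precision mode lands on the same 2-dp value
  cp_full <- derive_cutpoint(fit, threshold = 25)
  expect_equal(round(cp_full$cutpoint, 2), 0.53)
  # audit trail is internally consistent: predict(cutpoint) == required
  expect_equal(predict(fit, cp_full$cutpoint), cp_full$required_predicted,
               tolerance = 1e-9)
  td <- tidy(cp_full)
  expect_equal(td$cutpoint, cp_full$cutpoint)
  expect_false(td$paper_mode)
})

test_that("p = 0.5 collapses the chain to the plain inversion", {
  fit <- regression_summary(99.7, -24.7, n = 41, see = 4.1)
  cp <- derive_cutpoint(fit, threshold = 25, probability = 0.5)
  expect_equal(cp$cutpoint, (25 + 24.7) / 99.7, tolerance = 1e-12)
})

test_that("cut-points move monotonically in p, threshold and SEE", {
  mk <- function(see) regression_summary(99.7, -24.7, n = 41, see = see)
  cps_p <- vapply(c(0.6, 0.75, 0.9),
                  function(p) derive_cutpoint(mk(4.1), 25, p)$cutpoint,
                  numeric(1))
  expect_true(all(diff(cps_p) > 0))
  cps_thr <- vapply(c(20, 25, 30),
                    function(th) derive_cutpoint(mk(4.1), th)$cutpoint,
                    numeric(1))
  expect_true(all(diff(cps_thr) > 0))
  cps_see <- vapply(c(2, 4.1, 6),
                    function(s) derive_cutpoint(mk(s), 25)$cutpoint,
                    numeric(1))
  expect_true(all(diff(cps_see) >= 0))  # p > 0.5: more error, higher cut
  # vanishing prediction error collapses to the plain inversion at any p
  tiny <- derive_cutpoint(mk(1e-9), 25, probability = 0.9)
  expect_equal(tiny$cutpoint, (25 + 24.7) / 99.7, tolerance = 1e-8)
})

test_that("a derived cut-point is probability-calibrated under its own model", {
  set.seed(61)
  fit <- regression_summary(99.7, -24.7, n = 41, see = 4.1)
  cp <- derive_cutpoint(fit, threshold = 25, probability = 0.75)
  frac <- mc_exceedance(cp, n_draws = 2e5)
  expect_lt(abs(frac - 0.75), 4 * sqrt(0.75 * 0.25 / 2e5))
})

test_that("tertile thresholds put the top third strictly above the boundary", {
  def <- vat_tertile_threshold(1:9, sex = "M")
  expect_gte(def$tertile_boundary, 6)
  expect_lt(def$tertile_boundary, 7)
  expect_equal(def$n_above, 3)
  expect_equal(def$source_n, 9)
  # ceiling(n/3) +/- 1 membership across ragged sizes
  set.seed(62)
  for (n in c(7, 20, 32, 41, 100)) {
    v <- exp(rnorm(n, 6, 1))
    d <- vat_tertile_threshold(v)
    expect_lte(abs(d$n_above - ceiling(n / 3)), 1)
  }
  expect_error(vat_tertile_threshold(c(5, 7)),
               class = "adipocut_insufficient_data_error")
  expect_error(vat_tertile_threshold(c(3, 0, 4, 9)),
               class = "adipocut_domain_error")
  expect_error(vat_tertile_threshold(rep(7, 9)),
               class = "adipocut_degenerate_error")
})

test_that("VAT cut-points work on the ln-gram scale", {
  # zero-error identity fit: cut-point is the log boundary itself
  ident <- regression_summary(1, 0, n = 1e6, see = 1e-9,
                              outcome = "log_vat")
  def <- structure(list(sex = "M", tertile_boundary = exp(3), source_n = 30,
                        n_above = 10),
                   class = "vat_obesity_definition")
  cp <- derive_vat_cutpoint(ident, def)
  expect_equal(cp$cutpoint, 3, tolerance = 1e-6)
  expect_equal(cp$threshold_g, exp(3))

  # closed-form chain at full precision
  fit <- regression_summary(12.9, -0.04, n = 41, see = log(1.8),
                            outcome = "log_vat", predictor = "WHtR",
                            sex = "M")
  def2 <- vat_tertile_threshold(exp(rnorm(41, 6.4, 1)), sex = "M")
  cp2 <- derive_vat_cutpoint(fit, def2)
  expected <- (log(def2$tertile_boundary) +
                 qt(0.75, 39) * log(1.8) * sqrt(1 + 1 / 41 + 1 / 38) +
                 0.04) / 12.9
  expect_equal(cp2$cutpoint, expected, tolerance = 1e-9)

  wrong <- regression_summary(12.9, -0.04, n = 41, see = 0.6,
                              outcome = "fat_pct")
  expect_error(derive_vat_cutpoint(wrong, def2),
               class = "adipocut_consistency_error")
})

test_that("perfect fits are rejected by the cut-point chain", {
  fit <- fit_ols(1:6, (1:6) * 2)
  expect_error(derive_cutpoint(fit, 5), class = "adipocut_degenerate_error")
})
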
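# Independent least-squares oracle: normal equations via explicit matrix
# algebra, no call into the package's fitting path.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% beta
  rss <- sum(resid^2)
  list(intercept = beta[1], slope = beta[2], rss = rss,
       see = sqrt(rss / (length(x) - 2)))
}

# Monte-Carlo calibration oracle for a derived cut-point: simulate true
# outcomes around the prediction at the cut-point with t-distributed
# prediction error (the distribution under which the chain's probability
# statement is made) and measure the exceedance fraction.
mc_exceedance <- function(cp, n_draws = 1e6) {
  predicted <- cp$fit$intercept + cp$fit$slope * cp$cutpoint
  draws <- predicted + cp$see_adjusted * stats::rt(n_draws, df = cp$df)
  mean(draws > cp$threshold)
}

# Three-record cohort built in code, for I/O and indexing tests.
tiny_cohort <- function() {
  tibble::tibble(
    id = c("M001", "M002", "F001"),
    sex = c("M", "M", "F"),
    age_years = c(40, 55, 36),
    mass_kg = c(81, 95.5, 62.4),
    height_m = c(1.80, 1.776, 1.64),
    waist_cm = c(90, 88.8, 72.5),
    hip_cm = c(100, 101.3, 96),
    fat_pct = c(22.5, 27.9, 33.1),
    vat_g = c(850, 1210.5, 0)
  )
}

# A small cohort configuration that keeps simulation-based tests fast.
small_config <- function(n_m = 41, n_f = 40) {
  m <- default_male_config(); m$n <- n_m
  f <- default_female_config(); f$n <- n_f
  cohort_config(male = do.call(sex_config, unclass(m)),
                female = do.call(sex_config, unclass(f)))
}
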
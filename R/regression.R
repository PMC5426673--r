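#' Drop subjects with undetectable VAT
#'
#' VAT masses recorded as 0 g by the densitometry software cannot enter the
#' log-scale VAT models; they are removed before fitting. Percent-fat
#' analyses are unaffected by this filter.
#'
#' @param cohort A cohort tibble with a `vat_g` column.
#' @return A list with `retained` (tibble of rows with `vat_g > 0`) and
#'   `n_excluded` (integer count removed).
#' @export
exclude_undetectable_vat <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (!"vat_g" %in% names(cohort)) {
    abort("Cohort is missing column \"vat_g\".", class = "adipocut_input_error")
  }
  keep <- cohort$vat_g > 0
  list(retained = cohort[keep, , drop = FALSE],
       n_excluded = sum(!keep))
}

#' Simple linear regression of an outcome on one index
#'
#' Ordinary least squares via [stats::lm()], summarised with the quantities
#' the comparison and cut-point machinery needs: slope, intercept, residual
#' sum of squares, SEE = sqrt(RSS / (n - 2)), R^2, adjusted R^2 =
#' 1 - (1 - R^2)(n - 1)/(n - 2), and AIC (see [compute_aic()]). A perfect
#' fit (RSS = 0) is retained with `see = 0`, `adj_r2 = 1` and `aic = NA`;
#' downstream operations that need a positive prediction error reject it.
#'
#' @param x Predictor values.
#' @param y Outcome values, same length as `x`, n >= 4.
#' @param predictor,outcome,sex Optional labels carried into the result.
#' @return An object of class `"ols_fit"`.
#' @examples
#' fit_ols(1:5, c(2.1, 3.9, 6.2, 8.0, 9.8))
#' @export
fit_ols <- function(x, y, predictor = "x", outcome = "y", sex = NA_character_) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.",
          class = "adipocut_input_error")
  }
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) {
    abort("`x` and `y` must be finite.", class = "adipocut_input_error")
  }
  n <- length(x)
  if (n < 4) {
    abort(sprintf("Need at least 4 observations to fit (got %d).", n),
          class = "adipocut_insufficient_data_error")
  }
  if (var(x) == 0) {
    abort("Degenerate design: predictor is constant.",
          class = "adipocut_degenerate_error")
  }
  fit <- lm(y ~ x)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  perfect <- rss <= .Machine$double.eps * max(tss, 1)
  new_ols_fit(
    predictor = predictor, outcome = outcome, sex = sex, n = n,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    rss = rss,
    see = if (perfect) 0 else sqrt(rss / (n - 2)),
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
    aic = if (perfect) NA_real_ else aic_gaussian(n, rss)
  )
}

new_ols_fit <- function(predictor, outcome, sex, n, slope, intercept,
                        rss, see, r2, adj_r2, aic) {
  structure(
    list(predictor = predictor, outcome = outcome, sex = sex, n = n,
         slope = slope, intercept = intercept, rss = rss, see = see,
         r2 = r2, adj_r2 = adj_r2, aic = aic, df = n - 2),
    class = "ols_fit"
  )
}

#' Summarise a published regression as an `ols_fit`
#'
#' Builds the fit object the cut-point machinery consumes from reported
#' quantities (slope, intercept, n, SEE) when the subject-level data are not
#' available — e.g. to rework a published prediction equation. RSS and AIC
#' are reconstructed from SEE.
#'
#' @inheritParams fit_ols
#' @param slope,intercept Regression coefficients (outcome per predictor
#'   unit; outcome units).
#' @param n Number of subjects the fit used.
#' @param see Standard error of the estimate (outcome units), > 0.
#' @param adj_r2 Optional adjusted R^2.
#' @return An `"ols_fit"`.
#' @examples
#' regression_summary(slope = 99.7, intercept = -24.7, n = 41, see = 4.1,
#'                    predictor = "WHtR", outcome = "fat_pct", sex = "M")
#' @export
regression_summary <- function(slope, intercept, n, see,
                               predictor = "x", outcome = "y",
                               sex = NA_character_, adj_r2 = NA_real_) {
  if (!is.numeric(see) || see <= 0) {
    abort("`see` must be strictly positive.", class = "adipocut_domain_error")
  }
  if (n < 4) {
    abort("`n` must be at least 4.", class = "adipocut_insufficient_data_error")
  }
  rss <- see^2 * (n - 2)
  new_ols_fit(predictor = predictor, outcome = outcome, sex = sex, n = n,
              slope = slope, intercept = intercept, rss = rss, see = see,
              r2 = NA_real_, adj_r2 = adj_r2, aic = aic_gaussian(n, rss))
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> %s ~ %s%s, n = %d\n", x$outcome, x$predictor,
              if (is.na(x$sex)) "" else paste0(" [", x$sex, "]"), x$n))
  cat(sprintf("  %s = %.4g x %s %+.4g\n", x$outcome, x$slope, x$predictor,
              x$intercept))
  cat(sprintf("  SEE %.4g | adj R2 %s | AIC %s\n", x$see,
              formatC(x$adj_r2, format = "fg", digits = 3),
              formatC(x$aic, format = "fg", digits = 4)))
  invisible(x)
}

#' @export
predict.ols_fit <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' @rdname fit_ols
#' @param x An `ols_fit` (for the `tidy`/`glance` methods).
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.ols_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", x$predictor),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_ols
#' @export
#' @exportS3Method generics::glance
glance.ols_fit <- function(x, ...) {
  tibble(predictor = x$predictor, outcome = x$outcome, sex = x$sex,
         n = x$n, slope = x$slope, intercept = x$intercept, rss = x$rss,
         see = x$see, r.squared = x$r2, adj.r.squared = x$adj_r2,
         aic = x$aic, df = x$df)
}

# Gaussian maximum-likelihood profile AIC up to a constant shared by all
# candidates fitted to the same subjects: n ln(RSS/n) + 2k, k = 3 (slope,
# intercept, residual variance). Differences between candidates are
# constant-free, which is all the comparison scale uses.
aic_gaussian <- function(n, rss) {
  n * log(rss / n) + 2 * 3
}

#' Akaike information criterion of a simple-regression fit
#'
#' `AIC = n ln(RSS/n) + 2k` with `k = 3` parameters (slope, intercept,
#' residual variance). The value is defined only up to an additive constant
#' common to every candidate fitted to the same subjects, so only AIC
#' differences within a stratum are interpretable.
#'
#' @param fit An [fit_ols()] result.
#' @return The AIC (dimensionless scalar).
#' @export
compute_aic <- function(fit) {
  stopifnot(inherits(fit, "ols_fit"))
  if (fit$rss <= 0 || fit$see == 0) {
    abort("AIC is undefined for a perfect fit (RSS = 0).",
          class = "adipocut_degenerate_error")
  }
  aic_gaussian(fit$n, fit$rss)
}

#' Multiplicative 95% confidence factor for an SEE
#'
#' The residual variance of a Gaussian regression follows a scaled
#' chi-squared distribution, so the 95% CI of the SEE is multiplicative:
#' lower = SEE sqrt(df / chi2(0.975, df)), upper = SEE sqrt(df /
#' chi2(0.025, df)). `see_ci_factor()` condenses the interval into a single
#' symmetric x/: factor, the geometric mean of upper/SEE and SEE/lower;
#' `see_ci_bounds()` exposes the raw bounds.
#'
#' @param df Residual degrees of freedom (n - 2 for simple regression),
#'   >= 1.
#' @param see The SEE the bounds scale (default 1 gives pure factors).
#' @return `see_ci_factor()`: a scalar factor >= 1, decreasing in `df`.
#'   `see_ci_bounds()`: a one-row tibble with `lower`, `upper`, `factor`.
#' @examples
#' see_ci_factor(39)  # 1.25 at the degrees of freedom of a 41-subject fit
#' @export
see_ci_factor <- function(df) {
  if (!is.numeric(df) || any(df < 1)) {
    abort("`df` must be >= 1.", class = "adipocut_domain_error")
  }
  (qchisq(0.975, df) / qchisq(0.025, df))^(1 / 4)
}

#' @rdname see_ci_factor
#' @export
see_ci_bounds <- function(see = 1, df) {
  if (!is.numeric(see) || any(see <= 0)) {
    abort("`see` must be strictly positive.", class = "adipocut_domain_error")
  }
  if (!is.numeric(df) || any(df < 1)) {
    abort("`df` must be >= 1.", class = "adipocut_domain_error")
  }
  tibble(lower = see * sqrt(df / qchisq(0.975, df)),
         upper = see * sqrt(df / qchisq(0.025, df)),
         factor = see_ci_factor(df))
}

#' Geometric mean and x/: factor SD of a log-normal outcome
#'
#' For positive skewed outcomes analysed on the log scale (here VAT mass),
#' dispersion is multiplicative: the geometric mean `exp(mean(ln x))` is
#' multiplied/divided by the factor SD `exp(sd(ln x))` (n - 1 sample SD,
#' natural logs).
#'
#' @param values Strictly positive numeric vector, length >= 2. Zeros
#'   (undetectable VAT) must be excluded first, see
#'   [exclude_undetectable_vat()].
#' @return A one-row tibble with `geo_mean`, `factor_sd`, `n`.
#' @examples
#' geometric_summary(c(1, exp(2)))  # geo mean e, factor exp(sqrt(2))
#' @export
geometric_summary <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    abort("`values` must be a numeric vector of length >= 2.",
          class = "adipocut_input_error")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("All values must be strictly positive (exclude undetectable zeros first).",
          class = "adipocut_domain_error")
  }
  lv <- log(values)
  tibble(geo_mean = exp(mean(lv)), factor_sd = exp(sd(lv)),
         n = length(values))
}

#' Fit all five candidate index models, stratified by sex
#'
#' For each sex and each of BMI, WC, WHR, WHtR and WHT.5R, fits the simple
#' regression of the chosen outcome on the index. For `outcome =
#' "log_vat"`, subjects with undetectable (0 g) VAT are excluded per
#' stratum before taking natural logs.
#'
#' @param data A cohort tibble that already carries the index columns (see
#'   [add_indices()]).
#' @param outcome `"fat_pct"` (percent fat mass) or `"log_vat"` (ln VAT
#'   mass in grams).
#' @return A tibble with one row per sex x predictor: the [glance]
#'   columns of each fit plus a `fit` list-column of `ols_fit` objects and
#'   `n_excluded` (zero-VAT subjects removed from the stratum).
#' @examples
#' simulate_cohort(seed = 1) |>
#'   add_indices() |>
#'   fit_index_models("fat_pct")
#' @export
fit_index_models <- function(data, outcome = c("fat_pct", "log_vat")) {
  outcome <- match.arg(outcome)
  data <- as_tibble(data)
  cols <- index_columns()
  needed <- c(unname(cols), "sex",
              if (outcome == "fat_pct") "fat_pct" else "vat_g")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Missing column(s): %s. Run add_indices() first?",
                  paste0("\"", missing, "\"", collapse = ", ")),
          class = "adipocut_input_error")
  }
  purrr::map_dfr(c("M", "F"), function(s) {
    stratum <- dplyr::filter(data, .data$sex == s)
    n_excluded <- 0L
    if (outcome == "log_vat") {
      ex <- exclude_undetectable_vat(stratum)
      stratum <- ex$retained
      n_excluded <- ex$n_excluded
      y <- log(stratum$vat_g)
    } else {
      y <- stratum$fat_pct
    }
    purrr::map_dfr(names(cols), function(label) {
      fit <- fit_ols(stratum[[cols[[label]]]], y,
                     predictor = label, outcome = outcome, sex = s)
      dplyr::mutate(glance(fit), n_excluded = n_excluded,
                    fit = list(fit))
    })
  })
}
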
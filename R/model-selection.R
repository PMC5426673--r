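#' Rank candidate predictors within a stratum by AIC
#'
#' Computes each candidate's AIC difference from the stratum minimum and
#' attaches the qualitative support label used in information-theoretic
#' model comparison: essentially equivalent (delta < 2), plausible
#' alternative (2 <= delta <= 7), weak support (7 < delta <= 14),
#' unsupported (delta > 14). The printed scale overlaps at its boundaries
#' ("<2", "2-7", "7-14", ">14"); the half-open convention above is this
#' package's resolution and is exercised at each boundary by the test
#' suite. Exactly one row is labelled `"best"`; an exact AIC tie is broken
#' in favour of the predictor earliest in the canonical order BMI, WC, WHR,
#' WHtR, WHT.5R, with the other tied candidates labelled `"equivalent"` at
#' delta 0.
#'
#' @param fits Either the tibble returned by [fit_index_models()] (one
#'   stratum's rows, or both strata — each sex x outcome group is ranked
#'   separately), or a list of [fit_ols()] objects sharing sex, outcome and
#'   subjects.
#' @return A tibble of class `"aic_comparison"` with columns `sex`,
#'   `outcome`, `predictor`, `n`, `aic`, `aic_delta`, `delta_display` (the
#'   table-style string: `"0"`, `"<1"`, or the integer-rounded delta),
#'   `label`, `adj_r2`, `see`, `see_ci_factor`, `see_lower`, `see_upper`.
#' @examples
#' simulate_cohort(seed = 1) |>
#'   add_indices() |>
#'   fit_index_models("fat_pct") |>
#'   compare_models()
#' @export
compare_models <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits) &&
      all(purrr::map_lgl(fits, inherits, "ols_fit"))) {
    tab <- purrr::map_dfr(fits, glance)
    if (dplyr::n_distinct(tab$sex) > 1 || dplyr::n_distinct(tab$outcome) > 1) {
      abort("A list of fits must share one sex and one outcome (AIC comparison across different data is invalid).",
            class = "adipocut_consistency_error")
    }
    fits <- dplyr::mutate(tab, fit = fits)
  }
  fits <- as_tibble(fits)
  needed <- c("sex", "outcome", "predictor", "n", "aic", "adj_r2" = "adj.r.squared",
              "see", "df")
  missing <- setdiff(unname(needed), names(fits))
  if (length(missing) > 0) {
    abort(sprintf("`fits` is missing column(s): %s.",
                  paste0("\"", missing, "\"", collapse = ", ")),
          class = "adipocut_input_error")
  }
  if (any(!is.finite(fits$aic))) {
    abort("All candidate AICs must be finite (perfect fits cannot be compared).",
          class = "adipocut_degenerate_error")
  }
  out <- fits |>
    dplyr::group_by(.data$sex, .data$outcome) |>
    dplyr::group_modify(~ rank_stratum(.x)) |>
    dplyr::ungroup()
  class(out) <- c("aic_comparison", class(out))
  out
}

rank_stratum <- function(g) {
  if (dplyr::n_distinct(g$n) != 1) {
    abort("AIC comparison requires every candidate to be fitted to the same subjects (n differs within a stratum).",
          class = "adipocut_consistency_error")
  }
  if (anyDuplicated(g$predictor)) {
    abort("Duplicate predictor within a stratum.",
          class = "adipocut_consistency_error")
  }
  # canonical display/tie-break order
  ord <- order(match(g$predictor, index_labels()))
  g <- g[ord, , drop = FALSE]
  delta <- g$aic - min(g$aic)
  best <- which(delta <= 0)[1]  # first in canonical order among the minima
  label <- label_aic_delta(delta)
  label[best] <- "best"
  ci <- see_ci_bounds(g$see, g$df)
  tibble(
    predictor = g$predictor,
    n = g$n,
    aic = g$aic,
    aic_delta = delta,
    delta_display = format_aic_delta(delta, best = seq_along(delta) == best),
    label = label,
    adj_r2 = g$`adj.r.squared`,
    see = g$see,
    see_ci_factor = ci$factor,
    see_lower = ci$lower,
    see_upper = ci$upper
  )
}

#' Qualitative support label for an AIC difference
#'
#' @param delta Non-negative AIC difference(s) from the best candidate.
#' @return Character vector in `{"equivalent", "plausible", "weak",
#'   "unsupported"}` (the delta-0 best row is relabelled by
#'   [compare_models()]).
#' @export
label_aic_delta <- function(delta) {
  if (any(delta < 0)) {
    abort("AIC differences must be >= 0.", class = "adipocut_domain_error")
  }
  dplyr::case_when(
    delta < 2 ~ "equivalent",
    delta <= 7 ~ "plausible",
    delta <= 14 ~ "weak",
    TRUE ~ "unsupported"
  )
}

format_aic_delta <- function(delta, best) {
  dplyr::case_when(
    best ~ "0",
    delta > 0 & delta < 1 ~ "<1",
    TRUE ~ as.character(round(delta))
  )
}

#' @export
print.aic_comparison <- function(x, ...) {
  cat("# AIC comparison of candidate anthropometric predictors\n")
  NextMethod()
}

#' Bar chart of AIC differences per stratum
#'
#' @param object An [compare_models()] result.
#' @param ... Unused.
#' @return A ggplot: one bar per predictor (faceted by sex x outcome when
#'   several strata are present), dashed guides at the support-scale
#'   boundaries 2, 7 and 14.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.aic_comparison <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(predictor = factor(.data$predictor, levels = index_labels()))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$predictor,
                                        y = .data$aic_delta,
                                        fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(2, 7, 14), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "AIC difference from best model",
                  fill = "Support") +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(paste(df$sex, df$outcome)) > 1) {
    p <- p + ggplot2::facet_grid(outcome ~ sex)
  }
  p
}
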
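#' Run the full analysis pipeline on a cohort
#'
#' Computes, in order: the five indices; descriptive summaries per sex
#' (mean (SD) for indices and percent fat, geometric mean x/: factor SD for
#' detectable VAT, obesity prevalences); sex-stratified fits of percent fat
#' and ln VAT on each index; AIC comparison tables per stratum; and
#' probability-based cut-points for the best predictor of each stratum —
#' percent-fat cut-points against the sex-specific thresholds (25% men,
#' 35% women) and VAT cut-points against the sex-specific upper-tertile
#' boundary of detectable VAT.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()] /
#'   [read_cohort_csv()]).
#' @param probability Required probability of true exceedance (default
#'   0.75).
#' @param paper_mode Apply printed-precision intermediate rounding in the
#'   cut-point chains (default `FALSE`).
#' @param fm_thresholds Named vector of percent-fat obesity thresholds per
#'   sex.
#' @return A list of class `"adipo_report"`: `table1` (descriptives),
#'   `fits` (list with `fat_pct`, `log_vat` fit tables), `comparison`
#'   (single [compare_models()] tibble across strata), `vat_definitions`
#'   (per-sex [vat_tertile_threshold()] results) and `cutpoints` (tidy
#'   tibble of the four derivations, full audit trail).
#' @examples
#' rep <- simulate_cohort(seed = 42) |> run_report()
#' rep$cutpoints[, c("sex", "outcome", "predictor", "cutpoint")]
#' @export
run_report <- function(cohort, probability = 0.75, paper_mode = FALSE,
                       fm_thresholds = c(M = 25, F = 35)) {
  data <- add_indices(validate_cohort(cohort))
  fits_fm <- fit_index_models(data, "fat_pct")
  fits_vat <- fit_index_models(data, "log_vat")
  comparison <- compare_models(dplyr::bind_rows(fits_fm, fits_vat))

  best_fit <- function(fits, s) {
    g <- dplyr::filter(comparison, .data$sex == s,
                       .data$outcome == fits$outcome[1])
    best <- g$predictor[g$label == "best"]
    fits$fit[[which(fits$sex == s & fits$predictor == best)]]
  }

  vat_definitions <- purrr::map(c(M = "M", F = "F"), function(s) {
    v <- dplyr::filter(data, .data$sex == s)
    vat_tertile_threshold(exclude_undetectable_vat(v)$retained$vat_g, sex = s)
  })

  cutpoints <- dplyr::bind_rows(
    purrr::map_dfr(c("M", "F"), function(s) {
      derive_cutpoint(best_fit(fits_fm, s),
                      threshold = unname(fm_thresholds[[s]]),
                      probability = probability,
                      paper_mode = paper_mode) |> tidy()
    }),
    purrr::map_dfr(c("M", "F"), function(s) {
      cp <- derive_vat_cutpoint(best_fit(fits_vat, s), vat_definitions[[s]],
                                probability = probability,
                                paper_mode = paper_mode)
      dplyr::mutate(tidy(cp), threshold_g = cp$threshold_g)
    })
  )

  structure(
    list(table1 = cohort_table1(data),
         fits = list(fat_pct = fits_fm, log_vat = fits_vat),
         comparison = comparison,
         vat_definitions = vat_definitions,
         cutpoints = cutpoints,
         probability = probability, paper_mode = paper_mode),
    class = "adipo_report"
  )
}

#' Descriptive summary table per sex
#'
#' Mean (SD) rows for age, the five indices and percent fat; prevalence of
#' BMI- and percent-fat-defined obesity; and the geometric mean with x/:
#' factor SD for detectable VAT mass.
#'
#' @param data A cohort tibble with index columns (see [add_indices()]).
#' @return A tibble with one row per measure x sex: `measure`, `sex`, `n`,
#'   `value`, `dispersion`, `kind` (`"mean_sd"`, `"prevalence"` or
#'   `"geometric"`).
#' @export
cohort_table1 <- function(data) {
  data <- as_tibble(data)
  mean_sd_vars <- c(age_years = "Age (y)", bmi = "BMI (kg/m^2)",
                    waist_cm = "WC (cm)", whr = "WHR", whtr = "WHtR",
                    wht5r = "WHT.5R", fat_pct = "Total body fat mass (%)")
  purrr::map_dfr(c("M", "F"), function(s) {
    g <- dplyr::filter(data, .data$sex == s)
    msd <- purrr::imap_dfr(mean_sd_vars, function(label, col) {
      tibble(measure = label, sex = s, n = nrow(g),
             value = mean(g[[col]]), dispersion = sd(g[[col]]),
             kind = "mean_sd")
    })
    prev <- tibble(
      measure = c("BMI >= 30 kg/m^2",
                  if (s == "M") "FM > 25%" else "FM > 35%"),
      sex = s, n = nrow(g),
      value = c(mean(classify_bmi_obese(g$bmi)) * 100,
                mean(classify_fm_obese(g$sex, g$fat_pct)) * 100),
      dispersion = NA_real_, kind = "prevalence"
    )
    det <- exclude_undetectable_vat(g)$retained$vat_g
    geo <- geometric_summary(det)
    vat <- tibble(measure = "VAT mass (g)", sex = s, n = geo$n,
                  value = geo$geo_mean, dispersion = geo$factor_sd,
                  kind = "geometric")
    dplyr::bind_rows(msd, prev, vat)
  })
}

#' @export
print.adipo_report <- function(x, ...) {
  cat("== Anthropometric obesity cut-point report ==\n\n")
  cat("Descriptives (value (SD), % prevalence, or geometric mean x/: factor):\n")
  print(x$table1, n = Inf)
  cat("\nAIC comparison:\n")
  print(as_tibble(x$comparison)[, c("sex", "outcome", "predictor",
                                    "delta_display", "label", "adj_r2",
                                    "see")], n = Inf)
  cat(sprintf("\nCut-points (probability >= %.2f%s):\n", x$probability,
              if (x$paper_mode) ", printed-precision mode" else ""))
  print(x$cutpoints[, c("sex", "outcome", "predictor", "threshold",
                        "cutpoint")], n = Inf)
  invisible(x)
}

#' Write a report to disk
#'
#' Emits `table1.csv`, `comparison.csv`, `cutpoints.csv` and
#' `cutpoints.json` (full audit trail) under `dir`.
#'
#' @param report An [run_report()] result.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "adipo_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$table1, file.path(dir, "table1.csv"))
  readr::write_csv(as_tibble(report$comparison),
                   file.path(dir, "comparison.csv"))
  readr::write_csv(report$cutpoints, file.path(dir, "cutpoints.csv"))
  jsonlite::write_json(report$cutpoints, file.path(dir, "cutpoints.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
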
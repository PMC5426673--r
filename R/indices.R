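#' Add the five anthropometric indices to a cohort
#'
#' Appends `bmi` (kg/m^2, mass / height^2), `whr` (WC / HC), `whtr`
#' (WC / height, both in the same length units) and `wht5r`
#' (WC in metres / sqrt(height in metres)) to a cohort table; `waist_cm`
#' itself is the fifth candidate predictor. WHT.5R is the allometrically
#' scaled index; its conventional magnitude (about 0.67 in men) fixes the
#' units as metres over root-metres.
#'
#' @param cohort A cohort tibble with `mass_kg`, `height_m`, `waist_cm`,
#'   `hip_cm` (see [simulate_cohort()] / [read_cohort_csv()]).
#' @return The input tibble with index columns appended.
#' @examples
#' simulate_cohort(seed = 1) |> add_indices()
#' @export
add_indices <- function(cohort) {
  cohort <- as_tibble(cohort)
  needed <- c("mass_kg", "height_m", "waist_cm", "hip_cm")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    abort(sprintf("Cannot compute indices: missing column(s) %s.",
                  paste0("\"", missing, "\"", collapse = ", ")),
          class = "adipocut_input_error")
  }
  for (col in needed) {
    if (any(cohort[[col]] <= 0)) {
      abort(sprintf("Cannot compute indices: \"%s\" must be strictly positive.",
                    col),
            class = "adipocut_domain_error")
    }
  }
  cohort |>
    dplyr::mutate(
      bmi = .data$mass_kg / .data$height_m^2,
      whr = .data$waist_cm / .data$hip_cm,
      whtr = .data$waist_cm / (.data$height_m * 100),
      wht5r = (.data$waist_cm / 100) / sqrt(.data$height_m)
    )
}

#' Obesity classification by BMI
#'
#' `TRUE` iff BMI >= 30 kg/m^2 (boundary inclusive, per the WHO criterion).
#'
#' @param bmi Numeric vector of BMI values (kg/m^2).
#' @return Logical vector.
#' @export
classify_bmi_obese <- function(bmi) {
  if (!is.numeric(bmi) || any(!is.finite(bmi)) || any(bmi <= 0)) {
    abort("`bmi` must be finite and strictly positive.",
          class = "adipocut_domain_error")
  }
  bmi >= 30
}

#' Obesity classification by DXA percent fat mass
#'
#' Sex-specific thresholds, strict: men are obese above 25% fat, women above
#' 35% fat.
#'
#' @param sex Character vector of `"M"` / `"F"` codes (recycled against
#'   `fat_pct`).
#' @param fat_pct Numeric vector of whole-body fat percentages in (0, 100).
#' @return Logical vector.
#' @examples
#' classify_fm_obese(c("M", "M", "F"), c(25, 27.9, 35.1))
#' @export
classify_fm_obese <- function(sex, fat_pct) {
  if (any(sex %!in% c("M", "F"))) {
    abort(sprintf("Unknown sex code \"%s\" (expected \"M\" or \"F\").",
                  setdiff(sex, c("M", "F"))[1]),
          class = "adipocut_input_error")
  }
  if (!is.numeric(fat_pct) || any(!is.finite(fat_pct)) ||
      any(fat_pct <= 0 | fat_pct >= 100)) {
    abort("`fat_pct` must lie in (0, 100).", class = "adipocut_domain_error")
  }
  ifelse(sex == "M", fat_pct > 25, fat_pct > 35)
}
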
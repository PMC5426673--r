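#' Generate a synthetic cohort
#'
#' Draws one stratum per sex according to `config`. Indices are sampled
#' first — WHtR, BMI and WHR from truncated normals, height from a truncated
#' normal — and the raw measurements are back-derived so that every record
#' is internally consistent: WC = WHtR x height, HC = WC / WHR,
#' mass = BMI x height^2. Percent fat mass is `fm_intercept + fm_slope *
#' WHtR` plus Gaussian noise with SD `fm_see`; VAT mass is
#' `exp(logvat_intercept + logvat_slope * WHtR + e)` with ln-scale Gaussian
#' noise `e`, set to exactly 0 g (undetectable) with probability
#' `p_zero_vat`. Truncation floors (height > 1.2 m, WHtR > 0.25, BMI > 13,
#' WHR > 0.4, age >= 18 y, percent fat in (0, 100)) are enforced by
#' resampling and keep every measurement physically positive.
#'
#' The same `config` and `seed` always reproduce the identical cohort; the
#' male stratum is drawn first, then the female stratum, from one seeded
#' stream.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A tibble with one row per subject and columns `id`, `sex`
#'   (`"M"`/`"F"`), `age_years`, `mass_kg`, `height_m`, `waist_cm`,
#'   `hip_cm`, `fat_pct`, `vat_g`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(), seed = 1)
#' dplyr::count(cohort, sex)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  male <- simulate_stratum(config$male, sex = "M")
  female <- simulate_stratum(config$female, sex = "F")
  dplyr::bind_rows(male, female)
}

# Truncated-normal draw by rejection; `lower` is an open floor.
rnorm_trunc <- function(n, mean, sd, lower, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  guard <- 0L
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
    guard <- guard + 1L
    if (guard > 10000L) {
      abort("Truncation bounds reject essentially all draws; check the configuration.",
            class = "adipocut_config_error")
    }
  }
  x
}

simulate_stratum <- function(cfg, sex) {
  n <- cfg$n
  age <- rnorm_trunc(n, cfg$age_mean, cfg$age_sd, lower = 18 - 1e-9)
  height <- rnorm_trunc(n, cfg$height_mean, cfg$height_sd, lower = 1.2)
  whtr <- rnorm_trunc(n, cfg$whtr_mean, cfg$whtr_sd, lower = 0.25)
  bmi <- rnorm_trunc(n, cfg$bmi_mean, cfg$bmi_sd, lower = 13)
  whr <- rnorm_trunc(n, cfg$whr_mean, cfg$whr_sd, lower = 0.4)

  waist_cm <- whtr * height * 100
  hip_cm <- waist_cm / whr
  mass_kg <- bmi * height^2

  fat <- cfg$fm_intercept + cfg$fm_slope * whtr + rnorm(n, 0, cfg$fm_see)
  out <- which(fat <= 0 | fat >= 100)
  guard <- 0L
  while (length(out) > 0) {
    fat[out] <- cfg$fm_intercept + cfg$fm_slope * whtr[out] +
      rnorm(length(out), 0, cfg$fm_see)
    out <- out[fat[out] <= 0 | fat[out] >= 100]
    guard <- guard + 1L
    if (guard > 10000L) {
      abort("Percent fat mass model places essentially no mass in (0, 100).",
            class = "adipocut_config_error")
    }
  }

  vat <- exp(cfg$logvat_intercept + cfg$logvat_slope * whtr +
               rnorm(n, 0, cfg$logvat_see))
  vat[rbinom(n, 1, cfg$p_zero_vat) == 1L] <- 0

  tibble(
    id = sprintf("%s%03d", sex, seq_len(n)),
    sex = sex,
    age_years = age,
    mass_kg = mass_kg,
    height_m = height,
    waist_cm = waist_cm,
    hip_cm = hip_cm,
    fat_pct = fat,
    vat_g = vat
  )
}

cohort_csv_columns <- c("id", "sex", "age_years", "mass_kg", "height_cm",
                        "waist_cm", "hip_cm", "fat_pct", "vat_g")

#' Write / read a cohort CSV
#'
#' The on-disk schema uses centimetres for height
#' (`id, sex, age_years, mass_kg, height_cm, waist_cm, hip_cm, fat_pct,
#' vat_g`); in memory height is carried in metres. The reader validates the
#' header, numeric parsing, sex codes and sign constraints, reporting the
#' offending column or data row.
#'
#' @param cohort A cohort tibble as returned by [simulate_cohort()].
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a cohort tibble with `height_m`.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0) {
    abort("Refusing to write an empty cohort.", class = "adipocut_input_error")
  }
  out <- cohort |>
    dplyr::mutate(height_cm = .data$height_m * 100) |>
    dplyr::select(dplyr::all_of(cohort_csv_columns))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(cohort_csv_columns, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Cohort file is missing column(s): %s.",
                  paste0("\"", missing, "\"", collapse = ", ")),
          class = "adipocut_input_error")
  }
  numeric_cols <- setdiff(cohort_csv_columns, c("id", "sex"))
  parsed <- raw
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Column \"%s\": unparseable or missing numeric value at data row %d.",
                    col, bad[1]),
            class = "adipocut_input_error")
    }
    parsed[[col]] <- v
  }
  bad_sex <- which(parsed$sex %!in% c("M", "F"))
  if (length(bad_sex) > 0) {
    abort(sprintf("Unknown sex code \"%s\" at data row %d (expected \"M\" or \"F\").",
                  parsed$sex[bad_sex[1]], bad_sex[1]),
          class = "adipocut_input_error")
  }
  cohort <- parsed |>
    dplyr::mutate(height_m = .data$height_cm / 100) |>
    dplyr::select(dplyr::all_of(setdiff(cohort_csv_columns, "height_cm")),
                  "height_m") |>
    dplyr::relocate("height_m", .after = "mass_kg")
  validate_cohort(cohort)
}

# Shared record-level validation; errors name the column and first bad row.
validate_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  needed <- c("id", "sex", "age_years", "mass_kg", "height_m", "waist_cm",
              "hip_cm", "fat_pct", "vat_g")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    abort(sprintf("Cohort is missing column(s): %s.",
                  paste0("\"", missing, "\"", collapse = ", ")),
          class = "adipocut_input_error")
  }
  check_rows <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0) {
      abort(sprintf("%s at data row %d.", what, bad[1]),
            class = "adipocut_input_error")
    }
  }
  check_rows(cohort$sex %in% c("M", "F"), "Unknown sex code")
  for (col in c("mass_kg", "height_m", "waist_cm", "hip_cm")) {
    check_rows(cohort[[col]] > 0,
               sprintf("Non-positive \"%s\" (measurements must be > 0)", col))
  }
  check_rows(cohort$fat_pct > 0 & cohort$fat_pct < 100,
             "\"fat_pct\" outside (0, 100)")
  check_rows(cohort$vat_g >= 0, "Negative \"vat_g\" (mass cannot be negative)")
  cohort
}
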
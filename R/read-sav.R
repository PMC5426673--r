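#' Read a cohort from an SPSS .sav file
#'
#' Optional convenience for cohorts deposited in SPSS format. Requires the
#' `foreign` package. Column names in the file are mapped onto the cohort
#' schema via `col_map`; heights may be recorded in cm or m
#' (`height_unit`). Sex may be coded as a labelled factor — values are
#' normalised to `"M"`/`"F"` by their first letter (case-insensitive,
#' `male`/`female`, `1`/`2` with `1` = male).
#'
#' @param path Path to a `.sav` file.
#' @param col_map Named character vector mapping cohort fields (`id`,
#'   `sex`, `age_years`, `mass_kg`, `height`, `waist_cm`, `hip_cm`,
#'   `fat_pct`, `vat_g`) to column names in the file.
#' @param height_unit `"cm"` or `"m"`.
#' @return A validated cohort tibble (heights in metres).
#' @export
read_cohort_sav <- function(path,
                            col_map = c(id = "ID", sex = "Sex",
                                        age_years = "Age", mass_kg = "Mass",
                                        height = "Height",
                                        waist_cm = "WC", hip_cm = "HC",
                                        fat_pct = "FM", vat_g = "VAT"),
                            height_unit = c("cm", "m")) {
  height_unit <- match.arg(height_unit)
  if (!requireNamespace("foreign", quietly = TRUE)) {
    abort("Reading .sav files requires the `foreign` package.",
          class = "adipocut_input_error")
  }
  raw <- suppressWarnings(
    foreign::read.spss(path, to.data.frame = TRUE, use.value.labels = TRUE)
  )
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing) > 0) {
    abort(sprintf(".sav file is missing column(s): %s.",
                  paste0("\"", missing, "\"", collapse = ", ")),
          class = "adipocut_input_error")
  }
  sex_raw <- trimws(as.character(raw[[col_map[["sex"]]]]))
  sex <- dplyr::case_when(
    toupper(substr(sex_raw, 1, 1)) %in% c("M", "1") ~ "M",
    toupper(substr(sex_raw, 1, 1)) %in% c("F", "2") ~ "F",
    TRUE ~ NA_character_
  )
  height <- as.numeric(raw[[col_map[["height"]]]])
  cohort <- tibble(
    id = as.character(raw[[col_map[["id"]]]]),
    sex = sex,
    age_years = as.numeric(raw[[col_map[["age_years"]]]]),
    mass_kg = as.numeric(raw[[col_map[["mass_kg"]]]]),
    height_m = if (height_unit == "cm") height / 100 else height,
    waist_cm = as.numeric(raw[[col_map[["waist_cm"]]]]),
    hip_cm = as.numeric(raw[[col_map[["hip_cm"]]]]),
    fat_pct = as.numeric(raw[[col_map[["fat_pct"]]]]),
    vat_g = as.numeric(raw[[col_map[["vat_g"]]]])
  )
  validate_cohort(cohort)
}
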
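#' Cohort table schema
#'
#' The cohort is a plain tibble with one row per participant. These are the
#' required columns; `read_cohort()` enforces them and [validate_cohort()]
#' checks the row-level invariants.
#'
#' @format A character vector of column names.
#' @keywords internal
cohort_columns <- c(
  "id", "group", "gender", "age_years", "bmi", "body_weight_kg",
  "urine_conc_ug_per_L", "urine_detect", "urine_creatinine_mg_per_dL",
  "hair_conc_ng_per_g", "hair_detect"
)

cohort_numeric_columns <- c(
  "age_years", "bmi", "body_weight_kg", "urine_conc_ug_per_L",
  "urine_detect", "urine_creatinine_mg_per_dL", "hair_conc_ng_per_g",
  "hair_detect"
)

#' Detection limits used throughout the package
#'
#' Limits of detection (LOD) and quantitation (LOQ) of the HPLC-FLD method
#' for 2-hydroxynaphthalene: 0.2 ug/L (urine) and 0.2 ng/g (hair) for the
#' LOD, 1.17 in the same units for the LOQ.
#'
#' @return A list with elements `urine_lod`, `hair_lod`, `urine_loq`,
#'   `hair_loq`.
#' @export
#' @examples
#' detection_limits()
detection_limits <- function() {
  list(urine_lod = 0.2, hair_lod = 0.2, urine_loq = 1.17, hair_loq = 1.17)
}

#' Read a cohort table from a CSV file
#'
#' Reads a comma-separated, UTF-8, header-first cohort file (one row per
#' participant) and validates it. Columns: `id`, `group`
#' (polluted/control), `gender` (male/female), `age_years`, `bmi`,
#' `body_weight_kg`, `urine_conc_ug_per_L`, `urine_detect` (0/1),
#' `urine_creatinine_mg_per_dL`, `hair_conc_ng_per_g`, `hair_detect` (0/1).
#'
#' @param path Path to a CSV file.
#' @return A validated cohort tibble with typed columns (`urine_detect` and
#'   `hair_detect` as logical).
#' @export
#' @examples
#' path <- system.file("extdata", "example_cohort.csv", package = "naphrisk")
#' read_cohort(path)
read_cohort <- function(path) {
  if (!file.exists(path)) stop_param(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(cohort_columns, names(raw))
  if (length(missing)) {
    stop_schema(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0L) {
    out <- tibble(
      id = character(), group = character(), gender = character(),
      age_years = double(), bmi = double(), body_weight_kg = double(),
      urine_conc_ug_per_L = double(), urine_detect = logical(),
      urine_creatinine_mg_per_dL = double(),
      hair_conc_ng_per_g = double(), hair_detect = logical()
    )
    return(out)
  }
  for (col in cohort_numeric_columns) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(parsed))
    if (length(bad)) {
      stop_parse(sprintf("column `%s`: non-numeric value %s on row %d",
                         col, dQuote(raw[[col]][bad[1]]), bad[1]))
    }
    raw[[col]] <- parsed
  }
  cohort <- raw |>
    dplyr::select(dplyr::all_of(cohort_columns)) |>
    dplyr::mutate(
      urine_detect = .data$urine_detect > 0,
      hair_detect = .data$hair_detect > 0
    )
  validate_cohort(cohort)
}

#' Validate a cohort tibble
#'
#' Checks the participant invariants: unique ids, gender in
#' \{male, female\}, group in \{polluted, control\}, body weight > 0, age in
#' [18, 70], non-negative concentrations and creatinine. Violations raise an
#' error naming the offending row.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @return The cohort, invisibly unchanged, if valid.
#' @export
validate_cohort <- function(cohort) {
  missing <- setdiff(cohort_columns, names(cohort))
  if (length(missing)) {
    stop_schema(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  dup <- which(duplicated(cohort$id))
  if (length(dup)) {
    stop_integrity(sprintf("duplicate participant id %s on row %d",
                           dQuote(cohort$id[dup[1]]), dup[1]))
  }
  fail_row <- function(cond, what) {
    bad <- which(cond)
    if (length(bad)) {
      stop_integrity(sprintf("row %d: %s", bad[1], what))
    }
  }
  fail_row(!cohort$gender %in% c("male", "female"),
           "gender must be 'male' or 'female'")
  fail_row(!cohort$group %in% c("polluted", "control"),
           "group must be 'polluted' or 'control'")
  fail_row(!is.finite(cohort$body_weight_kg) | cohort$body_weight_kg <= 0,
           "body_weight_kg must be > 0")
  fail_row(!is.finite(cohort$age_years) | cohort$age_years < 18 |
             cohort$age_years > 70,
           "age_years must lie in [18, 70]")
  fail_row(is.finite(cohort$urine_conc_ug_per_L) &
             cohort$urine_conc_ug_per_L < 0,
           "urine_conc_ug_per_L must be >= 0")
  fail_row(is.finite(cohort$hair_conc_ng_per_g) &
             cohort$hair_conc_ng_per_g < 0,
           "hair_conc_ng_per_g must be >= 0")
  fail_row(is.finite(cohort$urine_creatinine_mg_per_dL) &
             cohort$urine_creatinine_mg_per_dL <= 0,
           "urine_creatinine_mg_per_dL must be > 0")
  cohort
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: detect flags are written as 0/1.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort |>
    dplyr::mutate(
      urine_detect = as.integer(.data$urine_detect),
      hair_detect = as.integer(.data$hair_detect)
    )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Reshape a cohort into a long measurement table
#'
#' One row per biomarker measurement (at most one urine and one hair row per
#' participant), carrying the raw value, detect flag, matrix-specific LOD and
#' LOQ, and (for urine) the creatinine concentration. This is the shape
#' consumed by [substitute_nondetects()].
#'
#' @param cohort A cohort tibble.
#' @param limits Detection/quantitation limits, as from [detection_limits()].
#' @return A tibble with columns `id`, `matrix` (urine/hair), `raw_value`,
#'   `detect`, `lod`, `loq`, `below_loq` (detects between LOD and LOQ,
#'   flagged for reporting but treated as valid), and
#'   `creatinine_mg_per_dL` (NA for hair rows).
#' @export
cohort_measurements <- function(cohort, limits = detection_limits()) {
  validate_cohort(cohort)
  urine <- cohort |>
    dplyr::transmute(
      id = .data$id, matrix = "urine",
      raw_value = .data$urine_conc_ug_per_L, detect = .data$urine_detect,
      lod = limits$urine_lod, loq = limits$urine_loq,
      creatinine_mg_per_dL = .data$urine_creatinine_mg_per_dL
    )
  hair <- cohort |>
    dplyr::transmute(
      id = .data$id, matrix = "hair",
      raw_value = .data$hair_conc_ng_per_g, detect = .data$hair_detect,
      lod = limits$hair_lod, loq = limits$hair_loq,
      creatinine_mg_per_dL = NA_real_
    )
  dplyr::bind_rows(urine, hair) |>
    dplyr::mutate(below_loq = .data$detect & .data$raw_value < .data$loq)
}

#' Substitute non-detects by half the detection limit
#'
#' Left-censored (non-detect) measurements are replaced by LOD/2 for risk
#' assessment and statistics. The raw value is preserved verbatim; the
#' substitution lands in a separate `working_value` column so it stays
#' auditable. Detects pass through unchanged. Idempotent.
#'
#' @param measurements A measurement tibble as from [cohort_measurements()],
#'   with at least `raw_value`, `detect` and `lod` columns.
#' @return A new tibble with a `working_value` column; the input is not
#'   modified.
#' @export
#' @examples
#' m <- tibble::tibble(raw_value = c(7.6, 0.05), detect = c(TRUE, FALSE),
#'                     lod = 0.2)
#' substitute_nondetects(m)
substitute_nondetects <- function(measurements) {
  needed <- c("raw_value", "detect", "lod")
  missing <- setdiff(needed, names(measurements))
  if (length(missing)) {
    stop_schema(sprintf("measurements need column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(measurements$lod) | measurements$lod <= 0)) {
    stop_param("every measurement must have lod > 0")
  }
  measurements |>
    dplyr::mutate(
      working_value = dplyr::if_else(.data$detect, .data$raw_value,
                                     .data$lod / 2)
    )
}

#' Creatinine normalisation of urinary concentrations
#'
#' Divides a urinary analyte concentration (ug/L) by the creatinine
#' concentration to correct for urine dilution. Creatinine is supplied in
#' mg/dL as clinically reported; it is converted to g/L internally
#' (1 mg/dL = 0.01 g/L), so the result is in ug analyte per g creatinine.
#'
#' @param c_u Urinary concentration, ug/L. Vectorised.
#' @param creatinine Urinary creatinine, mg/dL. Vectorised, recycled against
#'   `c_u`; must be strictly positive.
#' @return Creatinine-corrected concentration, ug/g creatinine.
#' @export
#' @examples
#' creatinine_correct(10, 100)   # 100 mg/dL = 1 g/L, so 10 ug/g
#' creatinine_correct(20.38, 144.326)
creatinine_correct <- function(c_u, creatinine) {
  if (any(!is.finite(creatinine) | creatinine <= 0)) {
    stop_param("`creatinine` must be > 0 (mg/dL)")
  }
  if (any(is.finite(c_u) & c_u < 0)) stop_param("`c_u` must be >= 0")
  c_u / (creatinine * 0.01)
}

#' Working measurement values for analysis
#'
#' Convenience wrapper applying the package's fixed analysis order: LOD/2
#' substitution first, then creatinine correction of the urine working
#' values. Returns the long measurement table with `working_value` and, for
#' urine rows, `corrected_ug_per_g` (ug/g creatinine).
#'
#' @inheritParams cohort_measurements
#' @return A measurement tibble with `working_value` and
#'   `corrected_ug_per_g` columns.
#' @export
analysis_values <- function(cohort, limits = detection_limits()) {
  m <- cohort_measurements(cohort, limits) |>
    substitute_nondetects()
  m$corrected_ug_per_g <- NA_real_
  urine <- m$matrix == "urine"
  m$corrected_ug_per_g[urine] <- creatinine_correct(
    m$working_value[urine], m$creatinine_mg_per_dL[urine]
  )
  m
}
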
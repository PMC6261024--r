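#' Fluid-chart format
#'
#' A fluid chart is a long-format tibble describing one or more patients over
#' one or two 8-hour epochs: one row per fluid flux, with the epoch-level
#' fields (weight, baseline sodium, measured final sodium) repeated on every
#' row of the epoch. An epoch with no recorded fluxes is represented by a
#' single row whose flux columns are `NA`.
#'
#' Columns (units are part of the contract; nothing is autodetected):
#' \describe{
#'   \item{patient_id}{character, opaque identifier.}
#'   \item{epoch}{`"epoch1"` or `"epoch2"`.}
#'   \item{weight_kg}{body weight in kg, > 0, measured at the epoch start.}
#'   \item{na_initial}{baseline serum sodium, mmol/L, in \[100, 200\].}
#'   \item{na_final_measured}{end-of-epoch serum sodium, mmol/L in
#'     \[100, 200\], or `NA` in pure-prediction mode.}
#'   \item{flux_kind}{one of `infused`, `drug`, `enteral`, `parenteral`
#'     (inputs) or `urine` (the only output kind); `NA` on a flux-free epoch
#'     row.}
#'   \item{volume_l}{flux volume in liters, >= 0.}
#'   \item{na_mmol_per_l}{sodium concentration of the flux, mmol/L, >= 0.}
#'   \item{k_mmol_per_l}{potassium concentration, mmol/L, >= 0; `NA` is read
#'     as 0 (unrecorded).}
#' }
#'
#' Sodium amounts (mmol) are always derived as concentration x volume, never
#' stored. At most one (aggregate) urine row is allowed per epoch. The urine
#' volume convention (same epoch vs preceding 8-h window, which the study
#' design treats as interchangeable) is left to the data preparer.
#'
#' @name chart-format
#' @aliases chart_columns
NULL

FLUX_KINDS <- c("infused", "drug", "enteral", "parenteral", "urine")
INPUT_KINDS <- setdiff(FLUX_KINDS, "urine")
EPOCH_LABELS <- c("epoch1", "epoch2")
SODIUM_PLAUSIBLE <- c(100, 200)

chart_cols <- c(
  "patient_id", "epoch", "weight_kg", "na_initial", "na_final_measured",
  "flux_kind", "volume_l", "na_mmol_per_l", "k_mmol_per_l"
)

#' Validate a fluid chart
#'
#' Checks a chart tibble against the format contract (see [chart-format]):
#' column presence, flux kinds, non-negative volumes and concentrations,
#' plausible sodium range \[100, 200\] mmol/L, positive weight, consistent
#' epoch-level fields within each patient-epoch, and at most one urine row
#' per epoch. All violations are collected and reported together as
#' `"row N: <message>"` lines (N is the data row, header excluded).
#'
#' @param chart A data frame in the chart format.
#' @return The validated chart as a tibble (potassium `NA` replaced by 0),
#'   invisibly usable in a pipe.
#' @examples
#' chart <- generate_cohort(n_patients = 2, seed = 1)
#' validate_chart(chart)
#' @export
validate_chart <- function(chart) {
  if (!is.data.frame(chart)) {
    abort_validation("`chart` must be a data frame.")
  }
  missing_cols <- setdiff(chart_cols, names(chart))
  if (length(missing_cols) > 0) {
    abort_parse(sprintf(
      "chart is missing mandatory column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  chart <- tibble::as_tibble(chart)[chart_cols]
  chart$patient_id <- as.character(chart$patient_id)
  chart$k_mmol_per_l <- dplyr::coalesce(as.numeric(chart$k_mmol_per_l), 0)

  issues <- character(0)
  note <- function(rows, msg) {
    if (length(rows) > 0) {
      issues <<- c(issues, sprintf("row %d: %s", rows, msg))
    }
  }

  has_flux <- !is.na(chart$flux_kind)
  note(which(has_flux & !chart$flux_kind %in% FLUX_KINDS),
       "unknown flux kind (expected infused/drug/enteral/parenteral/urine)")
  note(which(is.na(chart$epoch) | !chart$epoch %in% EPOCH_LABELS),
       "epoch must be 'epoch1' or 'epoch2'")
  note(which(is.na(chart$weight_kg) | chart$weight_kg <= 0),
       "weight must be a positive number of kg")
  note(which(has_flux & (is.na(chart$volume_l) | chart$volume_l < 0)),
       "negative or missing flux volume")
  note(which(has_flux & (is.na(chart$na_mmol_per_l) | chart$na_mmol_per_l < 0)),
       "negative or missing flux sodium concentration")
  note(which(has_flux & chart$k_mmol_per_l < 0),
       "negative flux potassium concentration")
  note(which(is.na(chart$na_initial) |
               chart$na_initial < SODIUM_PLAUSIBLE[1] |
               chart$na_initial > SODIUM_PLAUSIBLE[2]),
       "implausible sodium: na_initial outside [100, 200] mmol/L")
  note(which(!is.na(chart$na_final_measured) &
               (chart$na_final_measured < SODIUM_PLAUSIBLE[1] |
                  chart$na_final_measured > SODIUM_PLAUSIBLE[2])),
       "implausible sodium: na_final_measured outside [100, 200] mmol/L")

  # epoch-level fields must not vary within a patient-epoch
  key <- paste(chart$patient_id, chart$epoch, sep = "\r")
  for (col in c("weight_kg", "na_initial", "na_final_measured")) {
    n_distinct <- tapply(chart[[col]], key, function(x) length(unique(x)))
    bad_keys <- names(n_distinct)[n_distinct > 1]
    note(which(key %in% bad_keys),
         sprintf("%s differs across rows of the same patient-epoch", col))
  }
  urine_n <- tapply(chart$flux_kind == "urine", key, sum, na.rm = TRUE)
  multi_urine <- names(urine_n)[urine_n > 1]
  note(which(key %in% multi_urine & has_flux & chart$flux_kind == "urine"),
       "more than one urine row in this epoch (aggregate urine first)")

  if (length(issues) > 0) {
    abort_validation(c("invalid fluid chart:", stats::setNames(issues, rep("x", length(issues)))))
  }
  chart
}

#' Read a fluid chart from CSV
#'
#' Reads a UTF-8, header-mandatory CSV in the chart format (see
#' [chart-format]) and validates it. Rows violating the contract are
#' reported with their row numbers.
#'
#' @param path Path to a chart CSV file.
#' @return A validated chart tibble.
#' @seealso [write_chart()] for the inverse; the two round-trip.
#' @examples
#' path <- system.file("extdata", "synthetic_cohort_n10.csv", package = "natremia")
#' chart <- read_chart(path)
#' dplyr::count(chart, patient_id, epoch)
#' @export
read_chart <- function(path) {
  if (!file.exists(path)) {
    abort_parse(sprintf("chart file not found: %s", path))
  }
  # numeric fields come in as text and go through base strtod, which is
  # correctly rounded, so write_chart() round-trips bit-for-bit
  chart <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(chart_cols, names(chart))
  if (length(missing_cols) > 0) {
    abort_parse(sprintf(
      "chart CSV is missing mandatory column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  num_cols <- c("weight_kg", "na_initial", "na_final_measured",
                "volume_l", "na_mmol_per_l", "k_mmol_per_l")
  for (col in num_cols) {
    raw <- chart[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
    if (length(bad) > 0) {
      abort_parse(sprintf(
        "chart CSV has non-numeric value '%s' in column %s (row %d).",
        raw[bad[1]], col, bad[1]
      ))
    }
    chart[[col]] <- parsed
  }
  validate_chart(chart)
}

#' Write a fluid chart to CSV
#'
#' Writes a validated chart so that `read_chart(write_chart(x, path))`
#' reproduces `x` field-for-field. Numeric fields are written with enough
#' significant digits for an exact round-trip; empty cells encode `NA`
#' (absent final sodium, flux-free epochs).
#'
#' @param chart A chart tibble (validated before writing).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' chart <- generate_cohort(n_patients = 2, seed = 1)
#' path <- tempfile(fileext = ".csv")
#' write_chart(chart, path)
#' identical_cols <- all.equal(read_chart(path), chart)
#' @export
write_chart <- function(chart, path) {
  chart <- validate_chart(chart)
  out <- chart
  num_cols <- c("weight_kg", "na_initial", "na_final_measured",
                "volume_l", "na_mmol_per_l", "k_mmol_per_l")
  for (col in num_cols) {
    x <- out[[col]]
    out[[col]] <- ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Classify serum sodium into natremia categories
#'
#' Hyponatremia is serum sodium below 135 mmol/L and hypernatremia above
#' 145 mmol/L; both definitions are strict inequalities, so the boundary
#' values 135 and 145 classify as normonatremic.
#'
#' @param na Serum sodium, mmol/L; values outside \[100, 200\] are rejected
#'   as implausible.
#' @return A factor with levels `hyponatremic`, `normonatremic`,
#'   `hypernatremic`, same length as `na`.
#' @examples
#' classify_natremia(c(129, 135, 140, 145, 164))
#' @export
classify_natremia <- function(na) {
  check_number(na, "na", SODIUM_PLAUSIBLE[1], SODIUM_PLAUSIBLE[2])
  lab <- dplyr::case_when(
    na < 135 ~ "hyponatremic",
    na > 145 ~ "hypernatremic",
    .default = "normonatremic"
  )
  factor(lab, levels = c("hyponatremic", "normonatremic", "hypernatremic"))
}
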
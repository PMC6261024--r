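#' Total body water from actual body weight
#'
#' Estimates total body water (TBW) as a fixed fraction of measured body
#' weight. The default fraction 0.5 is applied to both sexes and all ages —
#' a deliberate bedside simplification (sex- and age-specific fractions are
#' more accurate; the fraction is configurable for that reason).
#'
#' @param weight_kg Body weight in kg, > 0. Vectorized.
#' @param fraction Water fraction of body weight, in (0, 1). Default
#'   [TBW_FRACTION_DEFAULT] (0.5).
#' @return TBW in liters.
#' @examples
#' total_body_water(70) # 35 L
#' total_body_water(70, fraction = 0.6)
#' @export
total_body_water <- function(weight_kg, fraction = TBW_FRACTION_DEFAULT) {
  check_number(weight_kg, "weight_kg", lower = 0, allow_zero_lower = FALSE)
  check_number(fraction, "fraction", lower = 0, upper = 1,
               allow_zero_lower = FALSE)
  if (any(fraction >= 1)) {
    abort_validation("`fraction` must be strictly below 1.")
  }
  weight_kg * fraction
}

#' Summarize the fluid and electrolyte balance of each epoch
#'
#' Aggregates a chart into one row per patient-epoch: total body water,
#' total input and output volumes, the signed net fluid balance
#' ("equilibrium" = inputs - outputs, liters), sodium and potassium amounts
#' (mmol, concentration x volume) on each side, and the urine stream's
#' volume and concentrations (0 when no urine was recorded).
#'
#' @param chart A chart tibble (see [chart-format]).
#' @param tbw_fraction Water fraction of body weight used for TBW.
#' @return A tibble with one row per patient-epoch and columns `patient_id`,
#'   `epoch`, `weight_kg`, `na_initial`, `na_final_measured`, `tbw`,
#'   `total_input_volume`, `total_output_volume`, `equilibrium`, `na_in`,
#'   `na_out`, `k_in`, `k_out`, `urine_volume`, `urine_na`, `urine_k`.
#' @examples
#' generate_cohort(n_patients = 3, seed = 1) |> summarize_balance()
#' @export
summarize_balance <- function(chart, tbw_fraction = TBW_FRACTION_DEFAULT) {
  chart <- validate_chart(chart)
  is_input <- !is.na(chart$flux_kind) & chart$flux_kind %in% INPUT_KINDS
  is_urine <- !is.na(chart$flux_kind) & chart$flux_kind == "urine"
  chart |>
    dplyr::mutate(
      .vol = dplyr::coalesce(.data$volume_l, 0),
      .na_amt = dplyr::coalesce(.data$na_mmol_per_l * .data$volume_l, 0),
      .k_amt = dplyr::coalesce(.data$k_mmol_per_l * .data$volume_l, 0),
      .in = is_input, .ur = is_urine
    ) |>
    dplyr::group_by(.data$patient_id, .data$epoch) |>
    dplyr::summarise(
      weight_kg = .data$weight_kg[1],
      na_initial = .data$na_initial[1],
      na_final_measured = .data$na_final_measured[1],
      tbw = total_body_water(.data$weight_kg[1], tbw_fraction),
      total_input_volume = sum(.data$.vol[.data$.in]),
      total_output_volume = sum(.data$.vol[.data$.ur]),
      na_in = sum(.data$.na_amt[.data$.in]),
      na_out = sum(.data$.na_amt[.data$.ur]),
      k_in = sum(.data$.k_amt[.data$.in]),
      k_out = sum(.data$.k_amt[.data$.ur]),
      urine_volume = sum(.data$.vol[.data$.ur]),
      urine_na = if (any(.data$.ur)) .data$na_mmol_per_l[.data$.ur][1] else 0,
      urine_k = if (any(.data$.ur)) .data$k_mmol_per_l[.data$.ur][1] else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      equilibrium = .data$total_input_volume - .data$total_output_volume,
      .after = "total_output_volume"
    )
}
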
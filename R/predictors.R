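#' Named constants of the prediction formulae
#'
#' `TBW_FRACTION_DEFAULT` (0.5) is the default water fraction of body
#' weight. `KURTZ_NGUYEN_OFFSET` (23.8 mmol/L) and `KURTZ_NGUYEN_SLOPE`
#' (1.03) are the intercept and electrolyte-gain coefficient of the
#' Kurtz-Nguyen formula, which models sodium in plasma water via the
#' empirical regression of exchangeable cations on body water.
#'
#' @name constants
#' @export
TBW_FRACTION_DEFAULT <- 0.5

#' @rdname constants
#' @export
KURTZ_NGUYEN_OFFSET <- 23.8

#' @rdname constants
#' @export
KURTZ_NGUYEN_SLOPE <- 1.03

PREDICTORS <- c("mass_balance", "adrogue_madias", "barsoum_levine",
                "kurtz_nguyen", "efwc")

check_denominator <- function(denom, what) {
  if (any(!is.finite(denom) | denom <= DENOM_EPS)) {
    abort_degenerate(sprintf(
      "degenerate balance: non-positive denominator in %s (end-of-epoch body water <= 0 L).",
      what
    ))
  }
  invisible(denom)
}

#' Mass-balance sodium prediction for chart epochs
#'
#' The mass-conservation predictor: sodium mass at the epoch start
#' (`na_initial` x TBW) plus sodium infused through every input stream
#' (fluids, drugs, enteral and parenteral nutrition; concentration x
#' volume) minus sodium excreted in urine, divided by the end-of-epoch body
#' water (TBW plus the signed net fluid balance, inputs - outputs).
#' Potassium never enters this formula. With no fluxes the prediction is
#' exactly `na_initial`.
#'
#' @param chart A chart tibble (see [chart-format]).
#' @param tbw_fraction Water fraction of body weight for TBW.
#' @return A tibble with one row per patient-epoch: `patient_id`, `epoch`,
#'   `predictor` (`"mass_balance"`), `na_predicted` (mmol/L).
#' @examples
#' generate_cohort(n_patients = 3, seed = 1) |> predict_mass_balance()
#' @export
predict_mass_balance <- function(chart, tbw_fraction = TBW_FRACTION_DEFAULT) {
  bal <- summarize_balance(chart, tbw_fraction)
  denom <- bal$tbw + bal$equilibrium
  if (any(denom <= DENOM_EPS)) {
    bad <- bal$patient_id[denom <= DENOM_EPS][1]
    abort_degenerate(sprintf(
      "degenerate balance for patient %s: TBW + equilibrium <= 0 L.", bad
    ))
  }
  tibble::tibble(
    patient_id = bal$patient_id,
    epoch = bal$epoch,
    predictor = "mass_balance",
    na_predicted = (bal$na_initial * bal$tbw + bal$na_in - bal$na_out) / denom
  )
}

#' Adrogue-Madias sodium prediction
#'
#' Closed-form prediction of serum sodium after infusing a volume of
#' solution, treating the body as a closed system (no renal losses, TBW
#' changes only by the infused volume):
#' `(na1 * tbw + vol_inf * na_k_inf_conc) / (tbw + vol_inf)`.
#' Originally derived per liter of infusate; arbitrary volumes are
#' accepted.
#'
#' @param na1 Baseline serum sodium, mmol/L. Vectorized with the rest.
#' @param tbw Total body water, liters.
#' @param vol_inf Infused volume, liters, >= 0.
#' @param na_k_inf_conc Combined sodium + potassium concentration of the
#'   infusate, mmol/L.
#' @return Predicted serum sodium, mmol/L.
#' @examples
#' predict_adrogue_madias(140, 35, 1, 154) # 1 L isotonic saline
#' predict_adrogue_madias(140, 35, 1, 0)   # 1 L electrolyte-free water
#' @export
predict_adrogue_madias <- function(na1, tbw, vol_inf, na_k_inf_conc) {
  denom <- tbw + vol_inf
  check_denominator(denom, "the Adrogue-Madias formula")
  (na1 * tbw + vol_inf * na_k_inf_conc) / denom
}

#' Barsoum-Levine sodium prediction
#'
#' Extends the Adrogue-Madias closed system with renal losses: electrolyte
#' amounts (mmol, not concentrations) gained and lost, and the net volume
#' change in the denominator:
#' `(na1 * tbw + na_k_in - na_k_out) / (tbw + vol_in - vol_out)`.
#'
#' @inheritParams predict_adrogue_madias
#' @param vol_in,vol_out Total input and output volumes, liters.
#' @param na_k_in,na_k_out Sodium + potassium amounts in inputs and
#'   outputs, mmol.
#' @return Predicted serum sodium, mmol/L.
#' @examples
#' predict_barsoum_levine(140, 35, vol_in = 1, na_k_in = 154,
#'                        vol_out = 1, na_k_out = 120)
#' @export
predict_barsoum_levine <- function(na1, tbw, vol_in, na_k_in, vol_out, na_k_out) {
  denom <- tbw + (vol_in - vol_out)
  check_denominator(denom, "the Barsoum-Levine formula")
  (na1 * tbw + na_k_in - na_k_out) / denom
}

#' Kurtz-Nguyen sodium prediction
#'
#' Models sodium concentration in plasma water rather than whole plasma,
#' via an affine map with offset [KURTZ_NGUYEN_OFFSET] (23.8 mmol/L) and
#' electrolyte-gain slope [KURTZ_NGUYEN_SLOPE] (1.03):
#' `((na1 + 23.8) * tbw + 1.03 * (na_k_in - na_k_out)) / (tbw + delta_vol) - 23.8`.
#'
#' @inheritParams predict_barsoum_levine
#' @param delta_vol Net volume change (inputs - outputs), liters.
#' @return Predicted serum sodium, mmol/L.
#' @examples
#' predict_kurtz_nguyen(140, 35, na_k_in = 100, na_k_out = 0, delta_vol = 0)
#' @export
predict_kurtz_nguyen <- function(na1, tbw, na_k_in, na_k_out, delta_vol) {
  denom <- tbw + delta_vol
  check_denominator(denom, "the Kurtz-Nguyen formula")
  ((na1 + KURTZ_NGUYEN_OFFSET) * tbw +
     KURTZ_NGUYEN_SLOPE * (na_k_in - na_k_out)) / denom - KURTZ_NGUYEN_OFFSET
}

#' Electrolyte-free water clearance (Rose)
#'
#' The portion of urine volume that is effectively solute-free water:
#' `vol_urine * (1 - (na_urine + k_urine) / na_serum)`. Negative when the
#' urine cation concentration exceeds serum sodium (the kidney is then
#' returning free water to the body).
#'
#' @param vol_urine Urine volume, liters, >= 0.
#' @param na_urine,k_urine Urine sodium and potassium concentrations, mmol/L.
#' @param na_serum Serum sodium, mmol/L, > 0 (measured at the epoch start).
#' @return EFWC in liters (may be negative).
#' @examples
#' efwc_rose(2, 50, 20, 140)  # dilute urine: +1 L free water cleared
#' efwc_rose(1, 160, 54, 107) # concentrated urine: negative clearance
#' @export
efwc_rose <- function(vol_urine, na_urine, k_urine, na_serum) {
  check_number(vol_urine, "vol_urine", lower = 0)
  if (any(!is.finite(na_serum) | na_serum <= 0)) {
    abort_validation("`na_serum` must be positive.")
  }
  vol_urine * (1 - (na_urine + k_urine) / na_serum)
}

#' EFWC-based sodium prediction
#'
#' Predicts serum sodium from renal free-water handling alone: the body
#' water shrinks (or grows) by the electrolyte-free water cleared, and the
#' sodium mass is assumed constant:
#' `na1 * tbw / (tbw - efwc)`. Infused water and sodium are not considered.
#'
#' @inheritParams predict_adrogue_madias
#' @param efwc Electrolyte-free water clearance over the epoch, liters
#'   (see [efwc_rose()]); may be negative.
#' @return Predicted serum sodium, mmol/L.
#' @examples
#' predict_efwc(140, 35, efwc = 1)
#' @export
predict_efwc <- function(na1, tbw, efwc) {
  denom <- tbw - efwc
  check_denominator(denom, "the EFWC formula")
  na1 * tbw / denom
}

#' Run every enabled predictor on each chart epoch
#'
#' Assembles each comparator's inputs from the epoch's balance summary
#' (total amounts and volumes over the whole epoch, not per liter) and
#' evaluates the enabled predictors. Potassium contributes to the
#' comparator formulae when recorded (and `include_potassium` is `TRUE`);
#' the mass-balance formula never includes it. A predictor that fails on an
#' epoch (e.g. a degenerate denominator) yields `NA` with the error message
#' in the `error` column; the other predictors are still evaluated.
#'
#' @param chart A chart tibble (see [chart-format]).
#' @param predictors Character vector of predictors to run; any of
#'   `"mass_balance"`, `"adrogue_madias"`, `"barsoum_levine"`,
#'   `"kurtz_nguyen"`, `"efwc"` (default all five).
#' @param tbw_fraction Water fraction of body weight for TBW.
#' @param include_potassium Should recorded potassium enter the comparator
#'   formulae? Default `TRUE`.
#' @return A tibble with one row per epoch x predictor: `patient_id`,
#'   `epoch`, `predictor`, `na_predicted`, `error` (`NA` unless the
#'   predictor failed on that epoch).
#' @examples
#' generate_cohort(n_patients = 3, seed = 1) |> predict_all()
#' @export
predict_all <- function(chart, predictors = PREDICTORS,
                        tbw_fraction = TBW_FRACTION_DEFAULT,
                        include_potassium = TRUE) {
  predictors <- match.arg(predictors, PREDICTORS, several.ok = TRUE)
  bal <- summarize_balance(chart, tbw_fraction)
  kf <- if (include_potassium) 1 else 0
  na_k_in <- bal$na_in + kf * bal$k_in
  na_k_out <- bal$na_out + kf * bal$k_out
  efwc <- efwc_rose(bal$urine_volume, bal$urine_na, kf * bal$urine_k,
                    bal$na_initial)

  # vectorized per predictor; degenerate epochs (denominator <= 0) are
  # tagged instead of aborting so the other predictors still evaluate
  one <- function(p) {
    denom <- switch(p,
      mass_balance = ,
      barsoum_levine = ,
      kurtz_nguyen = bal$tbw + bal$equilibrium,
      adrogue_madias = bal$tbw + bal$total_input_volume,
      efwc = bal$tbw - efwc
    )
    ok <- is.finite(denom) & denom > DENOM_EPS
    value <- rep(NA_real_, nrow(bal))
    value[ok] <- switch(p,
      mass_balance = (bal$na_initial * bal$tbw + bal$na_in - bal$na_out),
      adrogue_madias = ,
      barsoum_levine = (bal$na_initial * bal$tbw + na_k_in - kf_out(p) * na_k_out),
      kurtz_nguyen = (bal$na_initial + KURTZ_NGUYEN_OFFSET) * bal$tbw +
        KURTZ_NGUYEN_SLOPE * (na_k_in - na_k_out),
      efwc = bal$na_initial * bal$tbw
    )[ok] / denom[ok]
    if (p == "kurtz_nguyen") value[ok] <- value[ok] - KURTZ_NGUYEN_OFFSET
    tibble::tibble(
      patient_id = bal$patient_id, epoch = bal$epoch, predictor = p,
      na_predicted = value,
      error = ifelse(ok, NA_character_, sprintf(
        "%s (patient %s, %s): degenerate balance, non-positive denominator.",
        p, bal$patient_id, bal$epoch
      ))
    )
  }
  kf_out <- function(p) if (p == "adrogue_madias") 0 else 1

  dplyr::arrange(
    purrr::map_dfr(predictors, one),
    .data$patient_id, .data$epoch
  )
}
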
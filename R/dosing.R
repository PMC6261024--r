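#' Infusion volume needed to reach a target sodium
#'
#' Inverts the mass-balance predictor for the infusion volume: treating all
#' charted fluxes as fixed and adding an extra infusion of the chosen
#' solution, the balance equation is linear in the unknown volume `V`
#' (which appears both in the sodium mass and, through the net fluid
#' balance, in the end-of-epoch body water):
#'
#' `V * (infusate_na - na_target) = na_target * (TBW + equilibrium) -
#'  (na_initial * TBW + na_in - na_out)`
#'
#' where `equilibrium`, `na_in` and `na_out` summarize the charted fluxes
#' only. A unique non-negative solution exists when the infusate tonicity
#' lies on the correct side of the target; otherwise the plan is returned
#' with `feasible = FALSE` and a reason (a negative solution is never
#' reinterpreted as fluid removal). When the epoch is already at the target
#' the required volume is 0.
#'
#' @param chart A chart tibble (see [chart-format]); one plan is produced
#'   per patient-epoch.
#' @param na_target Desired end-of-epoch serum sodium, mmol/L, in
#'   \[100, 200\].
#' @param infusate_na Sodium concentration of the solution to infuse,
#'   mmol/L, >= 0 (e.g. 154 for 0.9% saline, 513 for 3% saline, 0 for
#'   electrolyte-free water).
#' @param tbw_fraction Water fraction of body weight for TBW.
#' @return A tibble with one row per patient-epoch: `patient_id`, `epoch`,
#'   `na_target`, `infusate_na`, `volume_required` (liters, `NA` when
#'   infeasible), `na_projected` (forward prediction after the planned
#'   infusion), `feasible`, `reason`.
#' @examples
#' chart <- generate_cohort(n_patients = 2, seed = 1)
#' solve_infusion_volume(chart, na_target = 142, infusate_na = 154)
#' @export
solve_infusion_volume <- function(chart, na_target, infusate_na,
                                  tbw_fraction = TBW_FRACTION_DEFAULT) {
  check_number(na_target, "na_target", SODIUM_PLAUSIBLE[1], SODIUM_PLAUSIBLE[2])
  check_number(infusate_na, "infusate_na", lower = 0)
  bal <- summarize_balance(chart, tbw_fraction)

  purrr::map_dfr(seq_len(nrow(bal)), function(i) {
    row <- bal[i, ]
    # rhs = sodium mass missing at the target, relative to the charted state
    rhs <- na_target * (row$tbw + row$equilibrium) -
      (row$na_initial * row$tbw + row$na_in - row$na_out)
    coef <- infusate_na - na_target

    if (abs(rhs) < 1e-12) {
      volume <- 0
      feasible <- TRUE
      reason <- NA_character_
    } else if (abs(coef) < 1e-12) {
      abort(sprintf(
        "no solution for patient %s, %s: infusate tonicity equals target (%g mmol/L) but the epoch is not at target.",
        row$patient_id, row$epoch, na_target
      ), class = "natremia_no_solution_error")
    } else {
      volume <- rhs / coef
      if (volume < 0) {
        feasible <- FALSE
        reason <- sprintf(
          "infusate at %g mmol/L cannot move sodium from %.2f toward %g (solution volume would be negative)",
          infusate_na, row$na_initial, na_target
        )
        volume <- NA_real_
      } else {
        feasible <- TRUE
        reason <- NA_character_
      }
    }

    na_projected <- if (isTRUE(feasible)) {
      denom <- row$tbw + row$equilibrium + volume
      if (denom <= DENOM_EPS) {
        feasible <- FALSE
        reason <- "planned infusion leaves non-positive body water"
        volume <- NA_real_
        NA_real_
      } else {
        (row$na_initial * row$tbw + row$na_in + infusate_na * volume -
           row$na_out) / denom
      }
    } else {
      NA_real_
    }

    tibble::tibble(
      patient_id = row$patient_id, epoch = row$epoch,
      na_target = na_target, infusate_na = infusate_na,
      volume_required = volume, na_projected = na_projected,
      feasible = feasible, reason = reason
    )
  })
}
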
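# Builders for small in-memory charts used across the test files.

# One epoch with the given fluxes. `fluxes` is a list of lists with
# kind/volume/na/k (k defaults to 0, as on an unrecorded chart column).
make_epoch <- function(patient_id = "P1", epoch = "epoch1", weight = 70,
                       na_initial = 140, na_final = NA_real_,
                       fluxes = list()) {
  if (length(fluxes) == 0) {
    return(tibble::tibble(
      patient_id = patient_id, epoch = epoch, weight_kg = weight,
      na_initial = na_initial, na_final_measured = na_final,
      flux_kind = NA_character_, volume_l = NA_real_,
      na_mmol_per_l = NA_real_, k_mmol_per_l = NA_real_
    ))
  }
  purrr::map_dfr(fluxes, function(f) tibble::tibble(
    patient_id = patient_id, epoch = epoch, weight_kg = weight,
    na_initial = na_initial, na_final_measured = na_final,
    flux_kind = f$kind, volume_l = f$volume,
    na_mmol_per_l = f$na, k_mmol_per_l = f$k %||% 0
  ))
}

flux <- function(kind, volume, na, k = 0) {
  list(kind = kind, volume = volume, na = na, k = k)
}

`%||%` <- rlang::`%||%`

fixture_path <- function() {
  system.file("extdata", "synthetic_cohort_n10.csv", package = "natremia")
}
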
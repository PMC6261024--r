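#' Synthetic ICU cohort specification
#'
#' Parameters of the seeded generator in [generate_cohort()]. The defaults
#' describe a mixed medical-surgical ICU population with dysnatremias:
#' baseline sodium is a truncated normal (mean 143.5, SD 6 mmol/L, support
#' \[125, 165\]) drawn stratified so that roughly 10% of patients enroll
#' hyponatremic, 53% normonatremic and 37% hypernatremic; urine sodium is a
#' truncated normal (mean 99.2, SD 50 mmol/L, support \[10, 215\]); enteral
#' and parenteral streams are present in about 76% and 61% of epochs. Two
#' consecutive 8-h epochs per patient, with the second epoch starting from
#' the first epoch's (noise-free) mass-balance final sodium.
#'
#' The latent ground truth obeys the mass-balance equation exactly:
#' `na_final_measured` is the mass-balance prediction plus Gaussian
#' measurement noise (`measurement_noise_sd`, default 2 mmol/L; baseline
#' sodium is treated as known).
#'
#' @param n_patients Number of patients.
#' @param seed Integer RNG seed; the same spec and seed always reproduce
#'   the identical cohort.
#' @param weight_mean,weight_sd,weight_range Body-weight truncated normal,
#'   kg.
#' @param na_baseline_mean,na_baseline_sd,na_baseline_range Baseline-sodium
#'   truncated normal, mmol/L (further truncated within each dysnatremia
#'   stratum).
#' @param dysnatremia_mix Named or ordered numeric vector of length 3
#'   (hypo, normo, hyper proportions, must sum to 1) targeted by stratified
#'   baseline draws.
#' @param flux_model Data frame with one row per input kind (`kind`,
#'   `prob`, `vol_lo`, `vol_hi`, `na_lo`, `na_hi`, `k_lo`, `k_hi`):
#'   presence probability, uniform volume range (L) and uniform
#'   concentration ranges (mmol/L).
#' @param urine_prob Probability that an epoch has a urine stream.
#' @param urine_vol_range Uniform urine-volume range, liters per 8 h.
#' @param urine_na_mean,urine_na_sd,urine_na_range Urine-sodium truncated
#'   normal, mmol/L.
#' @param urine_k_range Uniform urine-potassium range, mmol/L.
#' @param measurement_noise_sd Gaussian SD added to the latent final
#'   sodium, mmol/L.
#' @param epochs_per_patient 1 or 2.
#' @return A `cohort_spec` list.
#' @seealso [generate_cohort()], [generate_fixture()]
#' @export
cohort_spec <- function(n_patients = 50,
                        seed = 1L,
                        weight_mean = 75, weight_sd = 15,
                        weight_range = c(40, 130),
                        na_baseline_mean = 143.5, na_baseline_sd = 6,
                        na_baseline_range = c(125, 165),
                        dysnatremia_mix = c(hypo = 0.10, normo = 0.53,
                                            hyper = 0.37),
                        flux_model = default_flux_model(),
                        urine_prob = 1,
                        urine_vol_range = c(0.5, 2.5),
                        urine_na_mean = 99.2, urine_na_sd = 50,
                        urine_na_range = c(10, 215),
                        urine_k_range = c(10, 60),
                        measurement_noise_sd = 2,
                        epochs_per_patient = 2L) {
  spec <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    weight_mean = weight_mean, weight_sd = weight_sd,
    weight_range = weight_range,
    na_baseline_mean = na_baseline_mean, na_baseline_sd = na_baseline_sd,
    na_baseline_range = na_baseline_range,
    dysnatremia_mix = unname(dysnatremia_mix),
    flux_model = flux_model,
    urine_prob = urine_prob, urine_vol_range = urine_vol_range,
    urine_na_mean = urine_na_mean, urine_na_sd = urine_na_sd,
    urine_na_range = urine_na_range, urine_k_range = urine_k_range,
    measurement_noise_sd = measurement_noise_sd,
    epochs_per_patient = as.integer(epochs_per_patient)
  )
  validate_spec(spec)
  structure(spec, class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_flux_model <- function() {
  tibble::tribble(
    ~kind,        ~prob, ~vol_lo, ~vol_hi, ~na_lo, ~na_hi, ~k_lo, ~k_hi,
    "infused",     0.90,    0.25,     2.0,      0,    154,     0,    20,
    "drug",        0.50,    0.05,     0.5,      0,    154,     0,     0,
    "enteral",    0.758,    0.20,     1.0,     20,    100,    10,    40,
    "parenteral", 0.607,    0.25,     1.5,      0,    154,     0,    30
  )
}

validate_spec <- function(spec) {
  if (spec$n_patients < 0) abort_validation("n_patients must be >= 0.")
  if (abs(sum(spec$dysnatremia_mix) - 1) > 1e-8 ||
      any(spec$dysnatremia_mix < 0) || length(spec$dysnatremia_mix) != 3) {
    abort_validation("dysnatremia_mix must be 3 non-negative proportions summing to 1.")
  }
  if (!spec$epochs_per_patient %in% c(1L, 2L)) {
    abort_validation("epochs_per_patient must be 1 or 2.")
  }
  ranges <- list(spec$weight_range, spec$na_baseline_range,
                 spec$urine_vol_range, spec$urine_na_range,
                 spec$urine_k_range)
  if (any(vapply(ranges, function(r) diff(r) <= 0, logical(1)))) {
    abort_validation("all ranges must be non-degenerate (lower < upper).")
  }
  if (spec$measurement_noise_sd < 0) {
    abort_validation("measurement_noise_sd must be >= 0.")
  }
  invisible(spec)
}

# Strata bounds for stratified baseline draws (intersected with the
# spec's overall truncation range).
strata_bounds <- function(range) {
  list(
    hypo = c(range[1], min(135, range[2])),
    normo = c(max(135, range[1]), min(145, range[2])),
    hyper = c(max(145, range[1]), range[2])
  )
}

#' Generate a synthetic ICU cohort chart
#'
#' Draws a seeded synthetic cohort of patient epochs in the chart format
#' (see [chart-format]). For each patient: weight and an enrollment
#' (epoch 1) baseline sodium stratified over the dysnatremia mix; for each
#' epoch: the input fluxes and urine stream of the flux model; the latent
#' true final sodium by the mass-balance equation; and
#' `na_final_measured` as truth plus Gaussian measurement noise. With two
#' epochs per patient, epoch 2 starts from epoch 1's latent (noise-free)
#' final sodium, emulating consecutive 8-h intervals.
#'
#' @param spec A [cohort_spec()]; individual parameters may be overridden
#'   through `...`.
#' @param ... Overrides passed to [cohort_spec()] when `spec` is missing
#'   (e.g. `generate_cohort(n_patients = 100, seed = 7)`).
#' @return A validated chart tibble.
#' @examples
#' chart <- generate_cohort(n_patients = 5, seed = 1)
#' dplyr::count(chart, patient_id, epoch)
#' @export
generate_cohort <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- cohort_spec(...)
  validate_spec(spec)
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  if (spec$n_patients == 0) return(empty_chart())
  bounds <- strata_bounds(spec$na_baseline_range)
  rows <- list()

  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("P%04d", i)
    weight <- rtruncnorm(1, spec$weight_mean, spec$weight_sd,
                         spec$weight_range[1], spec$weight_range[2])
    stratum <- sample(c("hypo", "normo", "hyper"), 1,
                      prob = spec$dysnatremia_mix)
    b <- bounds[[stratum]]
    na0 <- rtruncnorm(1, spec$na_baseline_mean, spec$na_baseline_sd,
                      b[1], b[2])

    for (e in seq_len(spec$epochs_per_patient)) {
      epoch <- EPOCH_LABELS[e]
      fluxes <- draw_fluxes(spec)
      truth <- latent_final_na(na0, weight, fluxes)
      na_meas <- truth + rnorm(1, 0, spec$measurement_noise_sd)
      na_meas <- min(max(na_meas, SODIUM_PLAUSIBLE[1]), SODIUM_PLAUSIBLE[2])

      n_flux <- nrow(fluxes)
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = pid, epoch = epoch, weight_kg = weight,
        na_initial = na0, na_final_measured = na_meas,
        flux_kind = if (n_flux > 0) fluxes$kind else NA_character_,
        volume_l = if (n_flux > 0) fluxes$volume else NA_real_,
        na_mmol_per_l = if (n_flux > 0) fluxes$na else NA_real_,
        k_mmol_per_l = if (n_flux > 0) fluxes$k else NA_real_
      )
      # next epoch starts from the latent state (kept inside the chart's
      # plausible-sodium contract)
      na0 <- min(max(truth, SODIUM_PLAUSIBLE[1]), SODIUM_PLAUSIBLE[2])
    }
  }
  validate_chart(dplyr::bind_rows(rows))
}

draw_fluxes <- function(spec) {
  fm <- spec$flux_model
  out <- list()
  for (j in seq_len(nrow(fm))) {
    if (runif(1) < fm$prob[j]) {
      out[[length(out) + 1]] <- tibble::tibble(
        kind = fm$kind[j],
        volume = runif(1, fm$vol_lo[j], fm$vol_hi[j]),
        na = runif(1, fm$na_lo[j], fm$na_hi[j]),
        k = if (fm$k_hi[j] > fm$k_lo[j]) {
          runif(1, fm$k_lo[j], fm$k_hi[j])
        } else {
          fm$k_lo[j]
        }
      )
    }
  }
  if (runif(1) < spec$urine_prob) {
    out[[length(out) + 1]] <- tibble::tibble(
      kind = "urine",
      volume = runif(1, spec$urine_vol_range[1], spec$urine_vol_range[2]),
      na = rtruncnorm(1, spec$urine_na_mean, spec$urine_na_sd,
                      spec$urine_na_range[1], spec$urine_na_range[2]),
      k = runif(1, spec$urine_k_range[1], spec$urine_k_range[2])
    )
  }
  dplyr::bind_rows(out)
}

# Mass-balance truth for one epoch's drawn fluxes (potassium excluded,
# as in the forward predictor).
latent_final_na <- function(na0, weight, fluxes) {
  tbw <- weight * TBW_FRACTION_DEFAULT
  if (nrow(fluxes) == 0) return(na0)
  is_in <- fluxes$kind != "urine"
  na_in <- sum(fluxes$na[is_in] * fluxes$volume[is_in])
  na_out <- sum(fluxes$na[!is_in] * fluxes$volume[!is_in])
  eq <- sum(fluxes$volume[is_in]) - sum(fluxes$volume[!is_in])
  (na0 * tbw + na_in - na_out) / (tbw + eq)
}

empty_chart <- function() {
  tibble::tibble(
    patient_id = character(0), epoch = character(0),
    weight_kg = numeric(0), na_initial = numeric(0),
    na_final_measured = numeric(0), flux_kind = character(0),
    volume_l = numeric(0), na_mmol_per_l = numeric(0),
    k_mmol_per_l = numeric(0)
  )
}

#' Write a synthetic cohort chart to a CSV fixture
#'
#' Generates a cohort with [generate_cohort()] and writes it with
#' [write_chart()]. Because both steps are deterministic under the spec's
#' seed, regenerating with the same spec reproduces the file byte for
#' byte. A small shipped fixture (`extdata/synthetic_cohort_n10.csv`,
#' n = 10, seed 42) is produced exactly this way.
#'
#' @inheritParams generate_cohort
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
generate_fixture <- function(path, spec = NULL, ...) {
  chart <- generate_cohort(spec = spec, ...)
  if (nrow(chart) == 0) {
    readr::write_csv(empty_chart(), path, na = "", progress = FALSE)
    return(invisible(path))
  }
  write_chart(chart, path)
}
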
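# Independent hand-algebra oracles: every expected value here is computed
# with plain arithmetic on the defining balance equations, never through
# package code, so the tests compare two independent routes.

# Final sodium by direct mass conservation over itemized streams.
oracle_mass_balance <- function(na1, tbw, in_vols = numeric(0),
                                in_concs = numeric(0),
                                urine_vol = 0, urine_na = 0) {
  numerator <- na1 * tbw + sum(in_vols * in_concs) - urine_na * urine_vol
  denominator <- tbw + (sum(in_vols) - urine_vol)
  numerator / denominator
}

oracle_adrogue_madias <- function(na1, tbw, v, c) {
  (na1 * tbw + v * c) / (tbw + v)
}

oracle_barsoum_levine <- function(na1, tbw, vin, ain, vout, aout) {
  (na1 * tbw + ain - aout) / (tbw + vin - vout)
}

oracle_kurtz_nguyen <- function(na1, tbw, ain, aout, dvol) {
  ((na1 + 23.8) * tbw + 1.03 * (ain - aout)) / (tbw + dvol) - 23.8
}

oracle_efwc_rose <- function(v, na_u, k_u, na_s) {
  v * (1 - (na_u + k_u) / na_s)
}

oracle_efwc_prediction <- function(na1, tbw, efwc) {
  na1 * tbw / (tbw - efwc)
}

# Infusion volume from first principles: solve the conservation equation
# for V by moving terms across the equality (no linear-solver shortcut).
oracle_infusion_volume <- function(na1, tbw, target, infusate,
                                   eq_other = 0, na_in_other = 0,
                                   na_out = 0) {
  (target * (tbw + eq_other) - (na1 * tbw + na_in_other - na_out)) /
    (infusate - target)
}

# Brute-force agreement statistics via explicit loops (no vectorized
# shortcuts shared with the implementation).
oracle_bland_altman <- function(pred, meas) {
  n <- length(pred)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- pred[i] - meas[i]
  bias <- sum(d) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (d[i] - bias)^2
  sd_d <- sqrt(ss / (n - 1))
  c(bias = bias, sd_diff = sd_d,
    loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d)
}

oracle_percentage_similarity <- function(pred, meas) {
  n <- length(pred)
  s <- numeric(n)
  for (i in seq_len(n)) s[i] <- 100 * ((pred[i] + meas[i]) / 2) / meas[i]
  ms <- sum(s) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (s[i] - ms)^2
  sd_s <- sqrt(ss / (n - 1))
  c(mean_similarity = ms, sd_similarity = sd_s,
    mean_pct_diff = ms - 100, cv = 100 * sd_s / ms)
}
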
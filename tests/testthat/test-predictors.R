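# Hand-algebra expected values are computed by the independent oracles in
# helper-oracles.R, frozen here where a closed form is printed.

test_that("mass-balance prediction matches hand algebra on single streams", {
  # no fluxes: identity
  expect_equal(predict_mass_balance(make_epoch())$na_predicted, 140)
  # 1 L isotonic saline: (140*35 + 154) / 36
  chart <- make_epoch(fluxes = list(flux("infused", 1, 154)))
  expect_equal(predict_mass_balance(chart)$na_predicted,
               oracle_mass_balance(140, 35, 1, 154), tolerance = 1e-12)
  expect_equal(predict_mass_balance(chart)$na_predicted, 140.38889,
               tolerance = 1e-6)
  # 1 L urine at 70 mmol/L: (4900 - 70) / 34
  chart <- make_epoch(fluxes = list(flux("urine", 1, 70)))
  expect_equal(predict_mass_balance(chart)$na_predicted,
               oracle_mass_balance(140, 35, urine_vol = 1, urine_na = 70),
               tolerance = 1e-12)
  expect_equal(predict_mass_balance(chart)$na_predicted, 142.05882,
               tolerance = 1e-6)
})

test_that("mass balance sums every input stream kind and excludes potassium", {
  chart <- make_epoch(fluxes = list(
    flux("infused", 0.8, 154, k = 20),
    flux("drug", 0.2, 30),
    flux("enteral", 0.5, 60, k = 40),
    flux("parenteral", 0.7, 100, k = 15),
    flux("urine", 1.2, 90, k = 35)
  ))
  expected <- oracle_mass_balance(
    140, 35,
    in_vols = c(0.8, 0.2, 0.5, 0.7), in_concs = c(154, 30, 60, 100),
    urine_vol = 1.2, urine_na = 90
  )
  expect_equal(predict_mass_balance(chart)$na_predicted, expected,
               tolerance = 1e-12)
})

test_that("comparator formulae reproduce their printed closed forms", {
  expect_equal(predict_adrogue_madias(140, 35, 0, 154), 140)
  expect_equal(predict_adrogue_madias(140, 35, 1, 154),
               oracle_adrogue_madias(140, 35, 1, 154), tolerance = 1e-12)
  expect_equal(predict_adrogue_madias(140, 35, 1, 0), 136.11111,
               tolerance = 1e-6) # pure water dilution
  expect_equal(predict_barsoum_levine(140, 35, 0, 0, 0, 0), 140)
  expect_equal(predict_barsoum_levine(140, 35, 1, 154, 1, 120), 140.97143,
               tolerance = 1e-6)
  expect_equal(predict_barsoum_levine(140, 35, 1, 154, 1, 120),
               oracle_barsoum_levine(140, 35, 1, 154, 1, 120),
               tolerance = 1e-12)
  # zero output reduces Barsoum-Levine to Adrogue-Madias
  expect_equal(predict_barsoum_levine(140, 35, 1, 154, 0, 0),
               predict_adrogue_madias(140, 35, 1, 154), tolerance = 1e-12)
  expect_equal(predict_kurtz_nguyen(140, 35, 0, 0, 0), 140)
  expect_equal(predict_kurtz_nguyen(140, 35, 100, 0, 0), 142.94286,
               tolerance = 1e-6)
  expect_equal(predict_kurtz_nguyen(140, 35, 0, 0, 1), 135.45,
               tolerance = 1e-6)
  expect_equal(predict_efwc(140, 35, 0), 140)
  expect_equal(predict_efwc(140, 35, 1), 144.11765, tolerance = 1e-6)
  expect_equal(predict_efwc(140, 35, -1), 136.11111, tolerance = 1e-6)
})

test_that("Kurtz-Nguyen constants are exported with their defined values", {
  expect_identical(KURTZ_NGUYEN_OFFSET, 23.8)
  expect_identical(KURTZ_NGUYEN_SLOPE, 1.03)
  expect_identical(TBW_FRACTION_DEFAULT, 0.5)
})

test_that("EFWC can be negative when urine is more concentrated than serum", {
  expect_equal(efwc_rose(0, 100, 50, 140), 0)
  expect_equal(efwc_rose(2, 50, 20, 140), 1)
  expect_equal(efwc_rose(1, 160, 54, 107), -1)
  expect_error(efwc_rose(1, 100, 0, 0), class = "natremia_validation_error")
})

test_that("every predictor returns na_initial exactly on flux-free epochs", {
  withr::with_seed(101, {
    for (i in 1:25) {
      na1 <- runif(1, 120, 160)
      w <- runif(1, 40, 120)
      chart <- make_epoch(na_initial = na1, weight = w)
      preds <- predict_all(chart)
      expect_identical(nrow(preds), 5L)
      expect_true(all(is.na(preds$error)))
      expect_equal(preds$na_predicted, rep(na1, 5), tolerance = 1e-14)
    }
  })
})

test_that("mass balance, Adrogue-Madias and Barsoum-Levine coincide on single potassium-free infusions", {
  withr::with_seed(202, {
    for (i in 1:100) {
      na1 <- runif(1, 120, 160)
      tbw <- runif(1, 20, 50)
      vol <- runif(1, 1e-3, 3)
      conc <- runif(1, 0, 513)
      chart <- make_epoch(weight = 2 * tbw, na_initial = na1,
                          fluxes = list(flux("infused", vol, conc)))
      preds <- predict_all(chart)
      v <- preds$na_predicted[match(
        c("mass_balance", "adrogue_madias", "barsoum_levine"),
        preds$predictor
      )]
      expect_lt(max(v) - min(v), 1e-9)
    }
  })
})

test_that("predictions are invariant to common scaling of volumes and TBW", {
  base <- make_epoch(weight = 70, fluxes = list(
    flux("infused", 1, 154), flux("enteral", 0.5, 40, k = 20),
    flux("urine", 1.2, 90, k = 30)
  ))
  for (c_scale in c(0.5, 2, 7)) {
    scaled <- base
    scaled$weight_kg <- base$weight_kg * c_scale
    scaled$volume_l <- base$volume_l * c_scale
    p0 <- predict_all(base)$na_predicted
    p1 <- predict_all(scaled)$na_predicted
    expect_equal(p1, p0, tolerance = 1e-12)
  }
})

test_that("mass balance is monotone in infused volume around the infusate tonicity", {
  vols <- seq(0.1, 3, by = 0.1)
  pred_at <- function(v, conc) {
    chart <- make_epoch(fluxes = list(flux("infused", v, conc)))
    predict_mass_balance(chart)$na_predicted
  }
  below <- vapply(vols, pred_at, numeric(1), conc = 100) # hypotonic vs 140
  above <- vapply(vols, pred_at, numeric(1), conc = 513) # hypertonic
  expect_true(all(diff(below) < 0))
  expect_true(all(diff(above) > 0))
})

test_that("degenerate denominators raise errors naming the formula or patient", {
  # urine output exceeding TBW plus inputs
  chart <- make_epoch(weight = 2, fluxes = list(flux("urine", 2, 80)))
  expect_error(predict_mass_balance(chart),
               class = "natremia_degenerate_error", regexp = "P1")
  expect_error(predict_efwc(140, 1, 2), class = "natremia_degenerate_error")
  expect_error(predict_kurtz_nguyen(140, 1, 0, 0, -2),
               class = "natremia_degenerate_error")
})

test_that("predict_all tags a failing predictor but evaluates the rest", {
  # equilibrium so negative that the net-volume denominators collapse,
  # while Adrogue-Madias (inputs only) still works
  chart <- make_epoch(weight = 4, fluxes = list(
    flux("infused", 0.2, 154), flux("urine", 3, 20)
  ))
  preds <- predict_all(chart)
  expect_identical(nrow(preds), 5L)
  failed <- preds[!is.na(preds$error), ]
  expect_true(all(c("mass_balance", "barsoum_levine", "kurtz_nguyen") %in%
                    failed$predictor))
  expect_match(failed$error[failed$predictor == "mass_balance"],
               "mass_balance")
  ok <- preds[is.na(preds$error), ]
  expect_true("adrogue_madias" %in% ok$predictor)
  expect_true(all(is.finite(ok$na_predicted)))
})

test_that("potassium can be excluded from the comparator formulae", {
  chart <- make_epoch(fluxes = list(
    flux("infused", 1, 100, k = 40), flux("urine", 1, 60, k = 30)
  ))
  with_k <- predict_all(chart, include_potassium = TRUE)
  no_k <- predict_all(chart, include_potassium = FALSE)
  # mass balance never uses potassium
  mb <- function(x) x$na_predicted[x$predictor == "mass_balance"]
  expect_equal(mb(with_k), mb(no_k))
  # comparators change
  bl <- function(x) x$na_predicted[x$predictor == "barsoum_levine"]
  expect_false(isTRUE(all.equal(bl(with_k), bl(no_k))))
  # and the no-potassium Barsoum-Levine equals the mass balance here
  expect_equal(bl(no_k), mb(no_k), tolerance = 1e-12)
})
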
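#' Bland-Altman bias and limits of agreement
#'
#' Method-comparison statistics on paired predicted and measured values.
#' Differences are taken as predicted - measured (so a negative bias means
#' the method under-predicts); the spread uses the sample (n-1) standard
#' deviation, and the 95% limits of agreement are bias +/- 1.96 SD.
#'
#' @param data A data frame holding the paired values.
#' @param predicted,measured Columns of `data` (tidy-select) with the
#'   method's predictions and the reference measurements, mmol/L.
#' @return A one-row tibble: `n`, `bias`, `sd_diff`, `loa_low`, `loa_high`.
#' @examples
#' d <- data.frame(pred = c(139, 140, 141), meas = c(140, 140, 140))
#' bland_altman(d, pred, meas)
#' @export
bland_altman <- function(data, predicted, measured) {
  p <- dplyr::pull(data, {{ predicted }})
  m <- dplyr::pull(data, {{ measured }})
  check_pairs(p, m)
  d <- p - m
  bias <- mean(d)
  sd_diff <- sd(d)
  tibble::tibble(
    n = length(d), bias = bias, sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff
  )
}

#' Percentage Similarity between predictions and measurements
#'
#' For each pair the similarity is the mean of the pair referenced to the
#' gold-standard measurement: `s = 100 * ((predicted + measured) / 2) /
#' measured` (percent; 100 means perfect agreement). Summaries are the mean
#' and sample SD of the per-pair similarities, the mean percentage
#' difference (`mean_similarity - 100`), and the coefficient of variation
#' `100 * sd_similarity / mean_similarity`.
#'
#' @inheritParams bland_altman
#' @return A one-row tibble: `n`, `mean_similarity`, `sd_similarity`,
#'   `mean_pct_diff`, `cv` (all in percent).
#' @examples
#' d <- data.frame(pred = c(110, 100), meas = c(100, 100))
#' percentage_similarity(d, pred, meas)
#' @export
percentage_similarity <- function(data, predicted, measured) {
  p <- dplyr::pull(data, {{ predicted }})
  m <- dplyr::pull(data, {{ measured }})
  check_pairs(p, m)
  if (any(m <= 0)) {
    abort_validation("all measured values must be positive for Percentage Similarity.")
  }
  s <- 100 * ((p + m) / 2) / m
  ms <- mean(s)
  ss <- sd(s)
  tibble::tibble(
    n = length(s), mean_similarity = ms, sd_similarity = ss,
    mean_pct_diff = ms - 100, cv = 100 * ss / ms
  )
}

check_pairs <- function(p, m) {
  if (length(p) != length(m)) {
    abort_validation("predicted and measured must have equal length.")
  }
  if (length(p) < 2) {
    abort("at least 2 pairs are required for agreement statistics.",
          class = "natremia_insufficient_data_error")
  }
  if (any(!is.finite(p)) || any(!is.finite(m))) {
    abort_validation("predicted and measured must be finite.")
  }
  invisible(NULL)
}

#' Evaluate predictors against measured sodium over a cohort
#'
#' Runs the enabled predictors on every epoch of the chart (see
#' [predict_all()]), pairs each prediction with the measured end-of-epoch
#' sodium, and computes Bland-Altman and Percentage Similarity summaries
#' per predictor, overall and within each natremia subgroup (assigned from
#' the epoch's baseline sodium, i.e. the enrollment value). Epochs where a
#' predictor errored are excluded from that predictor's reports and
#' counted in `n_errors`. Subgroups with fewer than 2 evaluable pairs are
#' omitted with a notice.
#'
#' @inheritParams predict_all
#' @return An object of class `na_evaluation`: use [tidy()] for the report
#'   table (one row per predictor x subgroup with Bland-Altman and
#'   similarity columns), [glance()] for a one-row overview,
#'   [ggplot2::autoplot()] or [agreement_plots()] for figures, and
#'   `$series` for the underlying paired values.
#' @examples
#' ev <- generate_cohort(n_patients = 30, seed = 1) |> evaluate_cohort()
#' tidy(ev)
#' glance(ev)
#' @export
evaluate_cohort <- function(chart, predictors = PREDICTORS,
                            tbw_fraction = TBW_FRACTION_DEFAULT,
                            include_potassium = TRUE) {
  chart <- validate_chart(chart)
  measured <- dplyr::distinct(
    chart, .data$patient_id, .data$epoch,
    .keep_all = TRUE
  )[c("patient_id", "epoch", "na_initial", "na_final_measured")]
  if (nrow(measured) == 0) {
    abort_validation("empty cohort: no epochs to evaluate.")
  }
  if (anyNA(measured$na_final_measured)) {
    abort_validation("every epoch must have na_final_measured to be evaluated.")
  }

  preds <- predict_all(chart, predictors, tbw_fraction, include_potassium)
  series <- preds |>
    dplyr::left_join(measured, by = c("patient_id", "epoch")) |>
    dplyr::mutate(subgroup = classify_natremia(.data$na_initial)) |>
    dplyr::rename(na_measured = "na_final_measured")

  subgroups <- c("all", levels(series$subgroup))
  reports <- purrr::map_dfr(unique(series$predictor), function(pred) {
    sp <- dplyr::filter(series, .data$predictor == pred)
    n_errors <- sum(!is.na(sp$error))
    sp <- dplyr::filter(sp, is.na(.data$error))
    purrr::map_dfr(subgroups, function(sg) {
      sel <- if (sg == "all") sp else dplyr::filter(sp, .data$subgroup == sg)
      if (nrow(sel) < 2) {
        if (nrow(sel) > 0 || sg == "all") {
          inform(sprintf(
            "subgroup '%s' for predictor '%s' has %d evaluable pair(s); report omitted.",
            sg, pred, nrow(sel)
          ))
        }
        return(NULL)
      }
      dplyr::bind_cols(
        tibble::tibble(predictor = pred, subgroup = sg, n_errors = n_errors),
        bland_altman(sel, "na_predicted", "na_measured"),
        dplyr::select(
          percentage_similarity(sel, "na_predicted", "na_measured"),
          -"n"
        )
      )
    })
  })

  structure(
    list(reports = reports, series = series,
         predictors = unique(series$predictor)),
    class = "na_evaluation"
  )
}

#' @method tidy na_evaluation
#' @export
tidy.na_evaluation <- function(x, ...) {
  x$reports
}

#' @method glance na_evaluation
#' @export
glance.na_evaluation <- function(x, ...) {
  all_rep <- dplyr::filter(x$reports, .data$subgroup == "all")
  tibble::tibble(
    n_epochs = length(unique(paste(x$series$patient_id, x$series$epoch))),
    n_predictors = length(x$predictors),
    n_reports = nrow(x$reports),
    best_predictor = all_rep$predictor[which.min(abs(all_rep$bias))],
    best_bias = all_rep$bias[which.min(abs(all_rep$bias))]
  )
}

#' @method print na_evaluation
#' @export
print.na_evaluation <- function(x, ...) {
  cat("<na_evaluation>", nrow(x$reports), "agreement report(s) over",
      length(unique(paste(x$series$patient_id, x$series$epoch))),
      "epoch(s)\n")
  all_rep <- dplyr::filter(x$reports, .data$subgroup == "all")
  for (i in seq_len(nrow(all_rep))) {
    r <- all_rep[i, ]
    cat(sprintf(
      "  %-15s n=%3d  bias %+6.3f  SD %5.3f  LoA [%+.3f, %+.3f]  similarity %6.2f%% (CV %.2f%%)\n",
      r$predictor, r$n, r$bias, r$sd_diff, r$loa_low, r$loa_high,
      r$mean_similarity, r$cv
    ))
  }
  invisible(x)
}

#' Write the agreement report table to CSV
#'
#' One row per predictor x subgroup with the Bland-Altman and Percentage
#' Similarity columns (`predictor`, `subgroup`, `n`, `bias`, `sd_diff`,
#' `loa_low`, `loa_high`, `mean_similarity`, `sd_similarity`,
#' `mean_pct_diff`, `cv`).
#'
#' @param evaluation An `na_evaluation` from [evaluate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "na_evaluation"))
  cols <- c("predictor", "subgroup", "n", "bias", "sd_diff", "loa_low",
            "loa_high", "mean_similarity", "sd_similarity", "mean_pct_diff",
            "cv")
  readr::write_csv(evaluation$reports[cols], path, progress = FALSE)
  invisible(path)
}
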
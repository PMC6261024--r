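#' Plot an evaluation
#'
#' `autoplot()` draws either Bland-Altman scatters (mean of each
#' predicted/measured pair against their difference, with the bias line
#' solid and the 95% limits of agreement dashed) or per-pair Percentage
#' Similarity histograms, faceted by predictor.
#'
#' @param object An `na_evaluation` from [evaluate_cohort()].
#' @param type `"bland_altman"` (default) or `"similarity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot na_evaluation
#' @examples
#' ev <- generate_cohort(n_patients = 30, seed = 1) |> evaluate_cohort()
#' ggplot2::autoplot(ev)
#' ggplot2::autoplot(ev, type = "similarity")
#' @export
autoplot.na_evaluation <- function(object,
                                   type = c("bland_altman", "similarity"),
                                   ...) {
  type <- match.arg(type)
  series <- dplyr::filter(object$series, is.na(.data$error))
  reports <- dplyr::filter(object$reports, .data$subgroup == "all")

  if (type == "bland_altman") {
    series <- dplyr::mutate(
      series,
      pair_mean = (.data$na_predicted + .data$na_measured) / 2,
      difference = .data$na_predicted - .data$na_measured
    )
    ggplot2::ggplot(series, ggplot2::aes(.data$pair_mean, .data$difference)) +
      ggplot2::geom_point(alpha = 0.5, size = 1) +
      ggplot2::geom_hline(data = reports,
                          ggplot2::aes(yintercept = .data$bias)) +
      ggplot2::geom_hline(data = reports,
                          ggplot2::aes(yintercept = .data$loa_low),
                          linetype = "dashed") +
      ggplot2::geom_hline(data = reports,
                          ggplot2::aes(yintercept = .data$loa_high),
                          linetype = "dashed") +
      ggplot2::facet_wrap(ggplot2::vars(.data$predictor)) +
      ggplot2::labs(
        x = "Mean of predicted and measured sodium (mmol/L)",
        y = "Predicted - measured (mmol/L)",
        title = "Bland-Altman agreement with measured sodium"
      ) +
      ggplot2::theme_bw()
  } else {
    series <- dplyr::mutate(
      series,
      similarity = 100 * ((.data$na_predicted + .data$na_measured) / 2) /
        .data$na_measured
    )
    ggplot2::ggplot(series, ggplot2::aes(.data$similarity)) +
      ggplot2::geom_histogram(bins = 30, fill = "grey40", colour = "white") +
      ggplot2::geom_vline(xintercept = 100, linetype = "dashed") +
      ggplot2::facet_wrap(ggplot2::vars(.data$predictor)) +
      ggplot2::labs(
        x = "Percentage similarity to measured sodium (%)",
        y = "Epochs",
        title = "Percentage Similarity distribution"
      ) +
      ggplot2::theme_bw()
  }
}

#' Write per-predictor agreement figures to files
#'
#' For each predictor with at least one evaluable pair, writes one
#' Bland-Altman scatter (`<predictor>_bland_altman.<ext>`) and one
#' Percentage Similarity histogram (`<predictor>_similarity.<ext>`) into
#' `dir`. Predictors with an empty series produce no file and a notice.
#'
#' @param evaluation An `na_evaluation` from [evaluate_cohort()].
#' @param dir Output directory (created if absent).
#' @param format `"png"` or `"pdf"`.
#' @param width,height Device size in inches.
#' @return Character vector of the files written, invisibly.
#' @export
agreement_plots <- function(evaluation, dir, format = c("png", "pdf"),
                            width = 5, height = 4) {
  stopifnot(inherits(evaluation, "na_evaluation"))
  format <- match.arg(format)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create plot directory: %s", dir))
  }

  written <- character(0)
  for (pred in evaluation$predictors) {
    sub <- structure(
      list(
        reports = dplyr::filter(evaluation$reports,
                                .data$predictor == pred,
                                .data$subgroup == "all"),
        series = dplyr::filter(evaluation$series, .data$predictor == pred,
                               is.na(.data$error)),
        predictors = pred
      ),
      class = "na_evaluation"
    )
    if (nrow(sub$series) == 0) {
      inform(sprintf("no evaluable pairs for predictor '%s'; no plot written.",
                     pred))
      next
    }
    for (type in c("bland_altman", "similarity")) {
      file <- file.path(dir, sprintf("%s_%s.%s", pred, type, format))
      ggplot2::ggsave(file, autoplot.na_evaluation(sub, type = type),
                      width = width, height = height, dpi = 150)
      written <- c(written, file)
    }
  }
  invisible(written)
}
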
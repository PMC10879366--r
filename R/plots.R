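#' Plot entropy score time series
#'
#' Line plot of each score over block time, optionally with LoR/RoR event
#' markers; facetted by patient when a `patient_id` column is present.
#'
#' @param scores Score tibble from [score_recording()] or [score_cohort()].
#' @param events Optional events tibble (`patient_id`, `lor_s`, `ror_s`).
#' @param score_names Scores to draw. Default all present.
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, events = NULL, score_names = NULL) {
  value_cols <- setdiff(names(scores), c("patient_id", "time_s"))
  score_names <- score_names %||% value_cols
  long <- tidyr::pivot_longer(scores, dplyr::all_of(score_names),
                              names_to = "score_name", values_to = "bits")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$bits,
                                          colour = .data$score_name)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "score (bits)", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    ev_long <- tidyr::pivot_longer(events, c("lor_s", "ror_s"),
                                   names_to = "event", values_to = "time_s")
    p <- p + ggplot2::geom_vline(data = ev_long,
                                 ggplot2::aes(xintercept = .data$time_s),
                                 linetype = "dotted")
  }
  if ("patient_id" %in% names(scores)) {
    p <- p + ggplot2::facet_wrap(~patient_id)
  }
  p
}

#' Accuracy summary plot of a responsiveness analysis
#'
#' Point-range plot of the accuracy and bootstrap confidence interval of
#' every score, facetted by contrast (LoR, RoR, combined).
#'
#' @param object A `responsiveness_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.responsiveness_eval <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$score_name, y = .data$accuracy)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "accuracy") +
    ggplot2::theme_minimal()
}
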
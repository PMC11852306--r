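#' Plot a signal record
#'
#' Stacked traces of the PPG, ECG and (when present) ABP channels; for
#' synthetic records the ground-truth R-peak times are marked.
#'
#' @param object A [bp_record()].
#' @param channels Channels to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bp_record <- function(object, channels = c("ppg", "ecg", "abp"), ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = dplyr::any_of(channels),
                            names_to = "channel", values_to = "value")
  df <- df[is.finite(df$value), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("Record %s", record_id(object)))
  truth <- record_truth(object)
  if (!is.null(truth) && "ecg" %in% channels) {
    marks <- tibble::tibble(time = truth$r_peak_times, channel = "ecg")
    p <- p + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$time),
                                 linetype = "dotted", alpha = 0.4)
  }
  p
}

#' Bland-Altman agreement plot
#'
#' @param object A `bp_bland_altman` object (see [bland_altman()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bp_bland_altman <- function(object, ...) {
  s <- object$stats
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = s$me, color = "red") +
    ggplot2::geom_hline(yintercept = c(s$lower, s$upper),
                        color = "red", linetype = "dashed") +
    ggplot2::labs(x = "mean of estimate and reference (mmHg)",
                  y = "estimate - reference (mmHg)",
                  title = sprintf("Bland-Altman: ME %.2f, limits [%.2f, %.2f] mmHg",
                                  s$me, s$lower, s$upper))
}

#' Plot per-subject confidence intervals
#'
#' Interval ranges per subject, colored by method — the per-subject view of
#' how the four constructions compare.
#'
#' @param cis Output of [subject_cis()].
#' @return A ggplot object.
#' @export
plot_subject_cis <- function(cis) {
  ggplot2::ggplot(cis, ggplot2::aes(x = .data$subject_id, y = .data$center,
                                    color = .data$method)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                             position = ggplot2::position_dodge(width = 0.6),
                             size = 0.25) +
    ggplot2::facet_wrap(ggplot2::vars(.data$target), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "BP (mmHg)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot the weighted-feature-decision error curve
#'
#' Mean cross-validated MSE against subset size, with the chosen size
#' marked.
#'
#' @param wfd A `bp_wfd` object (see [wfd_select()]).
#' @return A ggplot object.
#' @export
plot_wfd_curve <- function(wfd) {
  ggplot2::ggplot(wfd$bestmse,
                  ggplot2::aes(x = .data$n_features, y = .data$cv_mse)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = wfd$n, linetype = "dashed", color = "red") +
    ggplot2::labs(x = "top-n ranked features", y = "mean CV MSE",
                  title = sprintf("Weighted feature decision: n* = %d", wfd$n))
}
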
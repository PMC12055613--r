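# ggplot2 displays for each result type.

#' Plot a 2D keypoint track
#'
#' Landmark trajectories in image coordinates (y axis reversed to match the
#' top-left pixel origin), coloured by landmark.
#'
#' @param track A [keypoint_track()].
#' @return A ggplot object.
#' @export
plot_keypoint_track <- function(track) {
  ggplot2::ggplot(as_tibble(track),
                  ggplot2::aes(.data$x, .data$y, colour = .data$landmark)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = NULL,
                  title = "2D keypoint track")
}

#' Plot an EMG trial with its detected onset
#'
#' Rectified EMG against time, with the cue, the detection threshold and
#' the detected onset marked.
#'
#' @param trial An [emg_trial()].
#' @inheritParams detect_onset
#' @return A ggplot object.
#' @export
plot_emg_trial <- function(trial, k = 5, min_supra = 5, window = 200) {
  onset <- detect_onset(trial, k = k, min_supra = min_supra, window = window)
  df <- tibble(time_ms = trial$time_ms,
               rectified_mV = rectify(trial, window))
  cue <- trial_attr(trial, "cue_time")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$rectified_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = cue, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = onset$threshold_mV,
                        colour = "firebrick", linetype = "dotted") +
    ggplot2::labs(x = "time (ms)", y = "rectified EMG (mV)",
                  title = sprintf("%s trial: %s",
                                  onset$condition,
                                  if (is.na(onset$latency_ms)) "no onset"
                                  else sprintf("onset %.1f ms",
                                               onset$latency_ms)))
  if (!is.na(onset$latency_ms)) {
    p <- p + ggplot2::geom_vline(xintercept = cue + onset$latency_ms,
                                 colour = "firebrick")
  }
  p
}

#' Plot per-condition cumulative latency distributions
#'
#' The classic single-subject display of the three-cue paradigm: cumulative
#' probability of reaction time per condition, showing the ordering
#' VRT > VART > VSRT when the startling cue shortens latencies.
#'
#' @param summary A [summarize_conditions()] result.
#' @return A ggplot object.
#' @export
plot_latency_cdf <- function(summary) {
  ggplot2::ggplot(latency_cdf(summary),
                  ggplot2::aes(.data$latency_ms, .data$cum_prob,
                               colour = .data$condition)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "reaction time (ms)", y = "cumulative probability",
                  colour = NULL, title = "Latency distributions by cue")
}

#' Plot a correlation battery
#'
#' Spearman rho per measure against the target, significance after the
#' battery-wide Benjamini-Hochberg correction shown by fill.
#'
#' @param object A `correlation_table` from [correlation_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_table <- function(object, ...) {
  df <- as_tibble(object)
  df$measure <- factor(df$measure, levels = rev(df$measure))
  ggplot2::ggplot(df, ggplot2::aes(.data$rho, .data$measure,
                                   fill = .data$significant_after_bh)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Spearman rho", y = NULL, fill = "significant (BH)",
                  title = sprintf("Correlations with %s",
                                  attr(object, "target", exact = TRUE)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
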
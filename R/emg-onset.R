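#' Rectify an EMG trial
#'
#' Full-wave rectification after DC removal: the mean of the raw signal over
#' the 200 ms pre-cue window is subtracted (so electrode offset inflates
#' neither the baseline statistics nor the response), then the absolute
#' value is taken. All downstream onset logic operates on this
#' representation.
#'
#' @param trial An [emg_trial()].
#' @param window Pre-cue window used for DC estimation, ms.
#' @return Numeric rectified series, mV (same length as the trial).
#' @export
rectify <- function(trial, window = 200) {
  stopifnot_emg(trial)
  idx <- baseline_index(trial, window)
  abs(trial$voltage_mV - mean(trial$voltage_mV[idx]))
}

stopifnot_emg <- function(trial) {
  if (!inherits(trial, "emg_trial")) {
    stop_reach("expected an emg_trial().", "reachstart_error_invalid_trial")
  }
  invisible(trial)
}

baseline_index <- function(trial, window) {
  cue <- trial_attr(trial, "cue_time")
  if (cue < window) {
    stop_reach(sprintf("cue at %g ms leaves no %g ms baseline window.",
                       cue, window),
               "reachstart_error_insufficient_baseline")
  }
  which(trial$time_ms >= cue - window & trial$time_ms < cue)
}

#' Baseline statistics of the rectified pre-cue EMG
#'
#' Mean and SD of the rectified signal over the `window` ms immediately
#' preceding the cue — the reference against which the onset threshold
#' (mean + k x SD) is set.
#'
#' @inheritParams rectify
#' @return A list with `mean` and `sd`, both mV.
#' @export
baseline_stats <- function(trial, window = 200) {
  r <- rectify(trial, window)
  idx <- baseline_index(trial, window)
  x <- r[idx]
  list(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
}

#' Detect EMG response onset by baseline threshold crossing
#'
#' The response latency is the time from cue to the first sample of
#' rectified EMG exceeding `baseline mean + k x baseline SD`, where the
#' baseline is the 200 ms pre-cue window. To guard against single-sample
#' stimulus artifacts, a crossing only qualifies if the rectified signal
#' stays above threshold for at least `min_supra` ms; shorter crossings are
#' skipped and the result is flagged, replacing the manual review an
#' interactive analysis would apply. When no qualifying crossing exists the
#' latency is absent (`NA`), not an error.
#'
#' @inheritParams rectify
#' @param k Threshold multiplier on the baseline SD (5 by convention).
#' @param min_supra Minimum supra-threshold duration, ms.
#' @return A list of class `onset_result`: `latency_ms` (from cue; `NA` when
#'   nothing qualifies), `threshold_mV`, `baseline_mean_mV`,
#'   `baseline_sd_mV`, `flagged_artifact`, and the trial's `condition` and
#'   `trial_id`.
#' @examples
#' tr <- simulate_emg_trial("VART", true_onset = 780, seed = 2)
#' detect_onset(tr)$latency_ms
#' @export
detect_onset <- function(trial, k = 5, min_supra = 5, window = 200) {
  stopifnot_emg(trial)
  check_number(k, "k", lower = 0)
  check_number(min_supra, "min_supra", lower = 0)
  r <- rectify(trial, window)
  bs <- baseline_stats(trial, window)
  thr <- bs$mean + k * bs$sd

  fs <- trial_attr(trial, "sampling_rate")
  cue <- trial_attr(trial, "cue_time")
  i_cue <- which(trial$time_ms >= cue)[1]
  min_n <- max(1L, ceiling(min_supra * fs / 1000))

  post <- r[i_cue:length(r)] > thr
  runs <- rle(post)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  supra <- which(runs$values)
  qualifying <- supra[runs$lengths[supra] >= min_n]
  flagged <- length(supra) > length(qualifying) &&
    (length(qualifying) == 0 || any(supra[runs$lengths[supra] < min_n] <
                                      qualifying[1]))
  latency <- NA_real_
  if (length(qualifying) > 0) {
    i_on <- i_cue + starts[qualifying[1]] - 1
    latency <- trial$time_ms[i_on] - cue
  }
  structure(
    list(latency_ms = latency, threshold_mV = thr,
         baseline_mean_mV = bs$mean, baseline_sd_mV = bs$sd,
         flagged_artifact = flagged,
         condition = trial_attr(trial, "condition"),
         trial_id = trial_attr(trial, "trial_id")),
    class = "onset_result"
  )
}

#' @export
print.onset_result <- function(x, ...) {
  lat <- if (is.na(x$latency_ms)) "no onset detected"
         else sprintf("%.2f ms after cue", x$latency_ms)
  cat(sprintf("EMG onset [%s]: %s\n", x$condition, lat))
  cat(sprintf("  threshold %.4g mV (baseline %.4g +/- %.4g mV)%s\n",
              x$threshold_mV, x$baseline_mean_mV, x$baseline_sd_mV,
              if (x$flagged_artifact) "  [artifact skipped]" else ""))
  invisible(x)
}

#' Summarize onset latencies per condition and the StartReact effect
#'
#' Runs [detect_onset()] on every trial, then reports the mean and SD
#' latency per cue condition over trials with a detected onset (trials
#' without one are counted as excluded, not imputed). The StartReact
#' effect — the reaction-time shortening produced by a startling sound —
#' is `mean(VART) - mean(VSRT)` in ms.
#'
#' @param trials A trialset tibble from [simulate_trialset()] (or any tibble
#'   with a `trial` list-column of [emg_trial()] objects), or a bare list of
#'   trials.
#' @inheritParams detect_onset
#' @return A list of class `reaction_time_summary`: `conditions` (tibble
#'   with `condition`, `mean_ms`, `sd_ms`, `n_valid`, `n_excluded`),
#'   `startreact_ms`, and `onsets` (per-trial tibble). Has [tidy()] and
#'   [glance()] methods.
#' @export
summarize_conditions <- function(trials, k = 5, min_supra = 5, window = 200) {
  trial_list <- if (is.data.frame(trials) && "trial" %in% names(trials)) {
    trials$trial
  } else if (is.list(trials) && !is.data.frame(trials)) {
    trials
  } else {
    stop_reach("`trials` must be a trialset tibble or a list of emg_trial.",
               "reachstart_error_invalid_trial")
  }
  onsets <- purrr::map_dfr(trial_list, function(tr) {
    o <- detect_onset(tr, k = k, min_supra = min_supra, window = window)
    tibble(trial_id = o$trial_id, condition = o$condition,
           latency_ms = o$latency_ms, flagged_artifact = o$flagged_artifact)
  })
  if (is.data.frame(trials) && "trial_id" %in% names(trials)) {
    onsets$trial_id <- trials$trial_id
  }
  conds <- onsets |>
    dplyr::mutate(condition = factor(.data$condition,
                                     levels = c("VRT", "VART", "VSRT"))) |>
    dplyr::group_by(.data$condition, .drop = FALSE) |>
    dplyr::summarise(
      mean_ms = mean(.data$latency_ms[!is.na(.data$latency_ms)]),
      sd_ms = sd(.data$latency_ms[!is.na(.data$latency_ms)]),
      n_valid = sum(!is.na(.data$latency_ms)),
      n_excluded = sum(is.na(.data$latency_ms)),
      .groups = "drop"
    ) |>
    dplyr::mutate(condition = as.character(.data$condition))
  get_mean <- function(cd) conds$mean_ms[conds$condition == cd]
  if (conds$n_valid[conds$condition == "VART"] < 1 ||
      conds$n_valid[conds$condition == "VSRT"] < 1) {
    stop_reach("need at least one detected onset in each of VART and VSRT.",
               "reachstart_error_insufficient_data")
  }
  structure(
    list(conditions = conds,
         startreact_ms = get_mean("VART") - get_mean("VSRT"),
         onsets = onsets),
    class = "reaction_time_summary"
  )
}

#' @export
print.reaction_time_summary <- function(x, ...) {
  cat("Reaction-time summary (ms from cue)\n")
  print(x$conditions)
  cat(sprintf("StartReact effect (VART - VSRT): %.2f ms\n", x$startreact_ms))
  invisible(x)
}

#' Cumulative latency distribution per condition
#'
#' Empirical cumulative probability of the detected latencies per cue
#' condition, the tabular form behind the classic per-subject
#' cumulative-distribution display of the three cues.
#'
#' @param summary A [summarize_conditions()] result.
#' @return A tibble with `condition`, `latency_ms`, `cum_prob`.
#' @export
latency_cdf <- function(summary) {
  if (!inherits(summary, "reaction_time_summary")) {
    stop_reach("expected a reaction_time_summary.",
               "reachstart_error_invalid_trial")
  }
  summary$onsets |>
    dplyr::filter(!is.na(.data$latency_ms)) |>
    dplyr::group_by(.data$condition) |>
    dplyr::arrange(.data$latency_ms, .by_group = TRUE) |>
    dplyr::mutate(cum_prob = seq_along(.data$latency_ms) /
                    length(.data$latency_ms)) |>
    dplyr::ungroup()
}
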
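#' Cue-locked EMG trial container
#'
#' One trial of surface EMG around a visual reaction cue: a regularly
#' sampled voltage series (mV) with the sampling rate, the cue time and the
#' stimulus condition attached as attributes. Sample `i` is at time
#' `(i - 1) / sampling_rate` seconds from trial start. A full 200 ms
#' baseline window must precede the cue, so `cue_time >= 200` ms is
#' enforced at construction.
#'
#' Conditions follow the three-cue reaction paradigm: `VRT` (visual cue
#' alone), `VART` (visual + quiet sound) and `VSRT` (visual + loud,
#' startling sound).
#'
#' @param voltage Numeric voltage series in mV.
#' @param sampling_rate Sampling rate in Hz (> 0; 5000 in a typical rig).
#' @param cue_time Cue onset in ms from trial start (>= 200).
#' @param condition One of `"VRT"`, `"VART"`, `"VSRT"`.
#' @param trial_id Identifier string.
#' @param true_onset_ms Optional ground-truth response onset, ms from trial
#'   start (simulated trials only).
#' @return A tibble of class `emg_trial` with columns `time_ms`,
#'   `voltage_mV`.
#' @export
emg_trial <- function(voltage, sampling_rate = 5000, cue_time = 500,
                      condition = c("VRT", "VART", "VSRT"),
                      trial_id = "trial-1", true_onset_ms = NA_real_) {
  condition <- match.arg(condition)
  check_number(voltage, "voltage", class = "reachstart_error_invalid_trial")
  check_number(sampling_rate, "sampling_rate", lower = 1e-9,
               class = "reachstart_error_invalid_trial")
  check_number(cue_time, "cue_time", lower = 200,
               class = "reachstart_error_invalid_trial")
  if (length(voltage) < 1) {
    stop_reach("trial must contain at least one sample.",
               "reachstart_error_invalid_trial")
  }
  time_ms <- (seq_along(voltage) - 1) / sampling_rate * 1000
  if (cue_time >= max(time_ms)) {
    stop_reach("cue_time falls at or beyond the end of the trial.",
               "reachstart_error_invalid_trial")
  }
  structure(
    tibble(time_ms = time_ms, voltage_mV = as.numeric(voltage)),
    sampling_rate = as.numeric(sampling_rate),
    cue_time = as.numeric(cue_time),
    condition = condition,
    trial_id = as.character(trial_id),
    true_onset_ms = as.numeric(true_onset_ms),
    class = c("emg_trial", class(tibble()))
  )
}

trial_attr <- function(trial, what) attr(trial, what, exact = TRUE)

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("EMG trial %s  [%s]  %d samples @ %g Hz, cue %g ms\n",
              trial_attr(x, "trial_id"), trial_attr(x, "condition"),
              nrow(x), trial_attr(x, "sampling_rate"),
              trial_attr(x, "cue_time")))
  NextMethod()
}
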
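#' Simulate one cue-locked EMG trial with a known response onset
#'
#' Builds a voltage series as zero-mean Gaussian baseline noise with a
#' response burst under a rectangular envelope starting at `true_onset`.
#' The burst carrier alternates polarity at random with per-sample
#' magnitudes drawn from U(0.9, 1) times `burst_amplitude`, so its
#' rectified profile rises sharply at onset and stays well clear of zero —
#' the property an amplitude-threshold onset detector needs. The envelope
#' gates the background noise out while the burst is on (resting-state
#' electrode noise is swamped once the muscle contracts), so the rectified
#' burst never dips below a threshold set from baseline statistics. The
#' injected onset is stored on the trial as ground truth.
#'
#' @param condition `"VRT"`, `"VART"` or `"VSRT"`.
#' @param true_onset Response onset in ms from trial start; must lie after
#'   `cue_time` and the burst must fit inside the trial.
#' @param burst_amplitude Burst amplitude in mV (>= 0; 0 simulates a trial
#'   with no response).
#' @param burst_duration Burst length in ms.
#' @param baseline_sd SD of the Gaussian background noise, mV (>= 0).
#' @param sampling_rate Sampling rate, Hz.
#' @param trial_duration Trial length, ms.
#' @param cue_time Cue onset, ms from trial start (>= 200).
#' @param seed Integer seed or `NULL`.
#' @return An [emg_trial()] carrying `true_onset_ms`.
#' @examples
#' tr <- simulate_emg_trial("VSRT", true_onset = 750, seed = 1)
#' detect_onset(tr)
#' @export
simulate_emg_trial <- function(condition = "VRT", true_onset = 750,
                               burst_amplitude = 0.5, burst_duration = 150,
                               baseline_sd = 0.01, sampling_rate = 5000,
                               trial_duration = 1500, cue_time = 500,
                               seed = NULL) {
  check_number(true_onset, "true_onset", lower = 0,
               class = "reachstart_error_invalid_trial")
  check_number(burst_amplitude, "burst_amplitude", lower = 0,
               class = "reachstart_error_invalid_trial")
  check_number(burst_duration, "burst_duration", lower = 1e-9,
               class = "reachstart_error_invalid_trial")
  check_number(baseline_sd, "baseline_sd", lower = 0,
               class = "reachstart_error_invalid_trial")
  if (true_onset <= cue_time) {
    stop_reach("true_onset must fall after the cue.",
               "reachstart_error_invalid_trial")
  }
  if (true_onset + burst_duration > trial_duration) {
    stop_reach("burst does not fit inside the trial.",
               "reachstart_error_invalid_trial")
  }
  n <- round(trial_duration * sampling_rate / 1000)
  i_on <- floor(true_onset * sampling_rate / 1000) + 1
  i_off <- min(n, i_on + round(burst_duration * sampling_rate / 1000) - 1)
  v <- with_seed_or_not(seed, {
    v <- rnorm(n, 0, baseline_sd)
    if (burst_amplitude > 0) {
      nb <- i_off - i_on + 1
      carrier <- sample(c(-1, 1), nb, replace = TRUE) * runif(nb, 0.9, 1)
      v[i_on:i_off] <- burst_amplitude * carrier
    }
    v
  })
  emg_trial(v, sampling_rate = sampling_rate, cue_time = cue_time,
            condition = condition,
            true_onset_ms = if (burst_amplitude > 0) true_onset else NA_real_)
}

#' Per-condition latency model for the three-cue reaction paradigm
#'
#' Holds the latency mean and SD (ms from cue) of each cue condition, plus
#' the truncation window applied when latencies are drawn. The study-scale
#' defaults are the stroke-cohort condition means and SDs:
#' VRT 326 +/- 96, VART 274 +/- 89, VSRT 225 +/- 80 ms.
#'
#' @param means,sds Named numeric vectors over `VRT`, `VART`, `VSRT` (ms).
#' @param truncation Latency bounds `c(lower, upper)` in ms from cue;
#'   `upper = NA` lets [simulate_trialset()] derive it from the trial length
#'   so every burst fits.
#' @return A list of class `latency_model`.
#' @export
latency_model <- function(means = c(VRT = 326, VART = 274, VSRT = 225),
                          sds = c(VRT = 96, VART = 89, VSRT = 80),
                          truncation = c(50, NA)) {
  conds <- c("VRT", "VART", "VSRT")
  if (!all(conds %in% names(means)) || !all(conds %in% names(sds))) {
    stop_reach("means and sds must be named over VRT, VART, VSRT.",
               "reachstart_error_invalid_model")
  }
  check_number(unname(means[conds]), "means", lower = 0)
  check_number(unname(sds[conds]), "sds", lower = 0)
  structure(list(means = means[conds], sds = sds[conds],
                 truncation = truncation),
            class = "latency_model")
}

rtruncnorm_one <- function(n, mean, sd, lower, upper) {
  if (lower >= upper) {
    stop_reach("degenerate truncation window (lower >= upper).",
               "reachstart_error_invalid_model")
  }
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop_reach("zero-SD latency falls outside the truncation window.",
                 "reachstart_error_invalid_model")
    }
    return(rep(mean, n))
  }
  # inverse-CDF sampling restricted to [lower, upper]
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Simulate a randomized set of EMG trials across the three cue conditions
#'
#' Draws `n_per_condition` ground-truth latencies per condition from
#' truncated normal distributions given by a [latency_model()], simulates one
#' EMG trial per latency with [simulate_emg_trial()], and shuffles the
#' presentation order — the structure of a reaction-time session in which
#' the three cues are delivered in random order.
#'
#' @param latmodel A [latency_model()].
#' @param n_per_condition Trials per condition (>= 1; 20 in a typical
#'   session).
#' @param seed Integer seed or `NULL`.
#' @inheritParams simulate_emg_trial
#' @return A tibble with one row per trial: `trial_id`, `order`,
#'   `condition`, `true_latency_ms` (from cue) and a `trial` list-column of
#'   [emg_trial()] objects.
#' @examples
#' ts <- simulate_trialset(latency_model(), n_per_condition = 3, seed = 1)
#' summarize_conditions(ts)
#' @export
simulate_trialset <- function(latmodel = latency_model(),
                              n_per_condition = 20,
                              burst_amplitude = 0.5, burst_duration = 150,
                              baseline_sd = 0.01, sampling_rate = 5000,
                              trial_duration = 1500, cue_time = 500,
                              seed = NULL) {
  if (!inherits(latmodel, "latency_model")) {
    stop_reach("`latmodel` must be a latency_model().",
               "reachstart_error_invalid_model")
  }
  if (n_per_condition < 1) {
    stop_reach("n_per_condition must be >= 1.",
               "reachstart_error_invalid_model")
  }
  lower <- latmodel$truncation[1]
  upper <- latmodel$truncation[2]
  if (is.na(upper)) upper <- trial_duration - cue_time - burst_duration
  conds <- c("VRT", "VART", "VSRT")
  seeds <- derive_seeds(seed, 3 * n_per_condition + 2)

  lat <- with_seed_or_not(seeds[1], {
    purrr::map(conds, function(cd) {
      rtruncnorm_one(n_per_condition, latmodel$means[[cd]],
                     latmodel$sds[[cd]], lower, upper)
    })
  })
  out <- tibble(
    condition = rep(conds, each = n_per_condition),
    true_latency_ms = unlist(lat)
  )
  out <- with_seed_or_not(seeds[2], out[sample.int(nrow(out)), ])
  out$order <- seq_len(nrow(out))
  out$trial_id <- sprintf("trial-%03d", out$order)
  out$trial <- purrr::pmap(
    list(out$condition, out$true_latency_ms, seeds[2 + seq_len(nrow(out))]),
    function(cd, l, s) {
      simulate_emg_trial(cd, true_onset = cue_time + l,
                         burst_amplitude = burst_amplitude,
                         burst_duration = burst_duration,
                         baseline_sd = baseline_sd,
                         sampling_rate = sampling_rate,
                         trial_duration = trial_duration,
                         cue_time = cue_time, seed = s)
    }
  )
  out[c("trial_id", "order", "condition", "true_latency_ms", "trial")]
}
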
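# Shared builders and independent oracles used across the suite.

# 2D keypoint track from per-frame coordinate matrices (n x 2 each); a
# single frame is duplicated to meet the two-frame track minimum.
make_track2d <- function(shoulder, elbow, wrist, nape = NULL,
                         likelihood = 1, frame_rate = 15) {
  n_frames <- max(2, nrow(rbind(shoulder)))
  as_mat <- function(m) {
    m <- rbind(m)
    if (nrow(m) == 1) m <- m[rep(1, n_frames), , drop = FALSE]
    dimnames(m) <- NULL
    m
  }
  shoulder <- as_mat(shoulder); elbow <- as_mat(elbow); wrist <- as_mat(wrist)
  n <- nrow(shoulder)
  if (is.null(nape)) nape <- shoulder + matrix(c(-10, -20), n, 2, byrow = TRUE)
  nape <- as_mat(nape)
  lik <- function(lm) {
    if (is.list(likelihood)) likelihood[[lm]] else rep(likelihood, n)
  }
  df <- dplyr::bind_rows(lapply(
    list(shoulder = shoulder, elbow = elbow, wrist = wrist, nape = nape),
    function(m) tibble::tibble(frame = seq_len(n), x = m[, 1], y = m[, 2])
  ), .id = "landmark")
  df$likelihood <- unlist(lapply(c("shoulder", "elbow", "wrist", "nape"), lik))
  keypoint_track(df, frame_rate = frame_rate)
}

# law-of-cosines chord length for interior elbow angle theta (degrees)
chord_length <- function(theta_deg, l1, l2) {
  sqrt(l1^2 + l2^2 - 2 * l1 * l2 * cos(theta_deg * pi / 180))
}

# wrist position giving interior elbow angle theta, arm along +x from origin
arm_frame_2d <- function(theta_deg, l1 = 100, l2 = 80) {
  th <- theta_deg * pi / 180
  elbow <- c(l1, 0)
  dir_sh <- c(-1, 0) # elbow -> shoulder
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  wrist <- elbow + l2 * as.numeric(rot %*% dir_sh)
  list(shoulder = c(0, 0), elbow = elbow, wrist = wrist)
}

# naive sample-by-sample onset scan: crossing + sustained supra-threshold rule
oracle_onset <- function(trial, k = 5, min_supra = 5, window = 200) {
  cue <- attr(trial, "cue_time")
  fs <- attr(trial, "sampling_rate")
  base_idx <- which(trial$time_ms >= cue - window & trial$time_ms < cue)
  r <- abs(trial$voltage_mV - mean(trial$voltage_mV[base_idx]))
  thr <- mean(r[base_idx]) + k * stats::sd(r[base_idx])
  i_cue <- which(trial$time_ms >= cue)[1]
  min_n <- max(1L, ceiling(min_supra * fs / 1000))
  n <- length(r)
  i <- i_cue
  while (i <= n) {
    if (r[i] > thr) {
      j <- i
      while (j <= n && r[j] > thr) j <- j + 1
      if (j - i >= min_n) return(trial$time_ms[i] - cue)
      i <- j
    }
    i <- i + 1
  }
  NA_real_
}

expect_reach_error <- function(expr, class) {
  expect_error(expr, class = class)
}
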
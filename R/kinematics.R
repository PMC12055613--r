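#' Per-frame distance between two tracked landmarks
#'
#' Euclidean pixel distance between two named landmarks of a 2D keypoint
#' track, frame by frame. A frame is marked invalid when either landmark's
#' tracking confidence falls below `confidence_threshold`; the distance is
#' still computed so that the mask, not the value, carries the decision.
#'
#' @param track A [keypoint_track()].
#' @param landmark_a,landmark_b Landmark names present in the track.
#' @param confidence_threshold Minimum likelihood for a frame to count as
#'   valid, in \[0, 1\]. The default 0 keeps every frame, reproducing an
#'   unfiltered tracking export.
#' @return A tibble with columns `frame`, `distance` (pixels) and `valid`.
#' @examples
#' reach <- simulate_reach(arm_model(), camera_model())
#' distance_series(reach$track2d, "shoulder", "wrist")
#' @export
distance_series <- function(track, landmark_a, landmark_b,
                            confidence_threshold = 0) {
  if (!inherits(track, "keypoint_track")) {
    stop_reach("`track` must be a keypoint_track().", "reachstart_error_format")
  }
  check_number(confidence_threshold, "confidence_threshold", 0, 1)
  for (lm in c(landmark_a, landmark_b)) {
    if (!lm %in% track$landmark) {
      stop_reach(sprintf("landmark `%s` not present in track.", lm),
                 "reachstart_error_lookup")
    }
  }
  a <- dplyr::filter(track, .data$landmark == landmark_a) |>
    dplyr::arrange(.data$frame)
  b <- dplyr::filter(track, .data$landmark == landmark_b) |>
    dplyr::arrange(.data$frame)
  if (!identical(a$frame, b$frame)) {
    stop_reach("landmarks are not observed on the same frames.",
               "reachstart_error_format")
  }
  tibble(
    frame = a$frame,
    distance = sqrt((a$x - b$x)^2 + (a$y - b$y)^2),
    valid = a$likelihood >= confidence_threshold &
      b$likelihood >= confidence_threshold
  )
}

#' Index of Elbow Extension (IoEE) from a 2D keypoint track
#'
#' The IoEE summarises how far the elbow extends during a reach, from a
#' single uncalibrated camera view:
#'
#' \deqn{IoEE = \frac{\max d(shoulder, wrist)}
#'   {\max d(shoulder, elbow) + \max d(elbow, wrist)}}
#'
#' with each maximum taken independently over that pair's valid frames.
#' Because the ratio is dimensionless it needs no pixel-to-metre calibration,
#' and a camera azimuth that foreshortens all limb segments alike largely
#' cancels. For a rigid two-segment arm the triangle inequality bounds the
#' value in \[0, 1\]: 0 when the wrist never leaves the shoulder (full
#' flexion), 1 when shoulder, elbow and wrist become collinear (full
#' extension). Tracking noise can push the ratio above 1; the raw value is
#' reported and flagged rather than clipped, since an excess is evidence of
#' tracking error.
#'
#' @inheritParams distance_series
#' @return A list of class `ioee_result` with fields `ioee`,
#'   `max_shoulder_wrist`, `max_shoulder_elbow`, `max_elbow_wrist` (pixels),
#'   `n_valid_frames` (frames valid for all three pairs) and
#'   `exceeds_unity_flag`. Has [tidy()] and [glance()] methods.
#' @examples
#' reach <- simulate_reach(arm_model(elbow_angle = seq(60, 170, len = 30)),
#'                         camera_model())
#' compute_ioee(reach$track2d)
#' @export
compute_ioee <- function(track, confidence_threshold = 0) {
  pairs <- list(
    max_shoulder_wrist = c("shoulder", "wrist"),
    max_shoulder_elbow = c("shoulder", "elbow"),
    max_elbow_wrist = c("elbow", "wrist")
  )
  series <- purrr::map(pairs, function(p) {
    distance_series(track, p[1], p[2], confidence_threshold)
  })
  maxima <- numeric(0)
  for (nm in names(series)) {
    s <- series[[nm]]
    if (!any(s$valid)) {
      stop_reach(
        sprintf("no valid frames for the %s distance at threshold %g.",
                paste(pairs[[nm]], collapse = "-"), confidence_threshold),
        "reachstart_error_insufficient_data"
      )
    }
    maxima[[nm]] <- max(s$distance[s$valid])
  }
  denom <- maxima[["max_shoulder_elbow"]] + maxima[["max_elbow_wrist"]]
  if (denom <= 0) {
    stop_reach("degenerate track: zero segment extents.",
               "reachstart_error_insufficient_data")
  }
  ioee <- maxima[["max_shoulder_wrist"]] / denom
  n_valid <- sum(series[[1]]$valid & series[[2]]$valid & series[[3]]$valid)
  structure(
    list(ioee = unname(ioee),
         max_shoulder_wrist = maxima[["max_shoulder_wrist"]],
         max_shoulder_elbow = maxima[["max_shoulder_elbow"]],
         max_elbow_wrist = maxima[["max_elbow_wrist"]],
         n_valid_frames = n_valid,
         exceeds_unity_flag = ioee > 1),
    class = "ioee_result"
  )
}

#' @export
print.ioee_result <- function(x, ...) {
  cat(sprintf("Index of Elbow Extension: %.4f%s\n", x$ioee,
              if (x$exceeds_unity_flag) "  [exceeds 1: check tracking]" else ""))
  cat(sprintf("  max shoulder-wrist: %.2f px\n", x$max_shoulder_wrist))
  cat(sprintf("  max shoulder-elbow: %.2f px\n", x$max_shoulder_elbow))
  cat(sprintf("  max elbow-wrist:    %.2f px\n", x$max_elbow_wrist))
  cat(sprintf("  frames valid for all pairs: %d\n", x$n_valid_frames))
  invisible(x)
}

#' Interior elbow angle from one frame of 3D joint coordinates
#'
#' Angle at the elbow between the vectors elbow->shoulder and elbow->wrist,
#' via the dot product, in degrees in \[0, 180\]. The cosine is clamped to
#' \[-1, 1\] before `acos` so exactly collinear geometry does not produce
#' NaN from rounding.
#'
#' @param shoulder,elbow,wrist Length-3 numeric vectors (mm).
#' @return Angle in degrees.
#' @examples
#' elbow_angle_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)) # 180: full extension
#' @export
elbow_angle_frame <- function(shoulder, elbow, wrist) {
  for (p in list(shoulder, elbow, wrist)) check_number(p, "point")
  u <- shoulder - elbow
  v <- wrist - elbow
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop_reach("elbow coincides with shoulder or wrist: angle undefined.",
               "reachstart_error_degenerate_geometry")
  }
  rad2deg(acos(clip(sum(u * v) / (nu * nv), -1, 1)))
}

#' Maximum elbow angle over a 3D-tracked reach
#'
#' Computes the interior elbow angle for every frame of a [pose3d_track()]
#' and reports the per-frame series, its maximum and the frame attaining it —
#' the reference measure the IoEE is validated against. Frames with
#' degenerate geometry (elbow coincident with shoulder or wrist) are skipped
#' and counted.
#'
#' @param track A [pose3d_track()].
#' @return A list of class `elbow_angle_result` with `max_angle` (degrees),
#'   `frame_of_max`, `angles` (tibble: frame, angle_deg) and
#'   `n_degenerate_frames`.
#' @examples
#' reach <- simulate_reach(arm_model(elbow_angle = seq(60, 170, len = 30)))
#' max_elbow_angle(reach$track3d)$max_angle
#' @export
max_elbow_angle <- function(track) {
  if (!inherits(track, "pose3d_track")) {
    stop_reach("`track` must be a pose3d_track().", "reachstart_error_format")
  }
  wide <- track |>
    dplyr::filter(.data$landmark %in% c("shoulder", "elbow", "wrist")) |>
    tidyr::pivot_wider(id_cols = "frame", names_from = "landmark",
                       values_from = c("x_mm", "y_mm", "z_mm")) |>
    dplyr::arrange(.data$frame)

  angle_one <- function(i) {
    tryCatch(
      elbow_angle_frame(
        c(wide$x_mm_shoulder[i], wide$y_mm_shoulder[i], wide$z_mm_shoulder[i]),
        c(wide$x_mm_elbow[i], wide$y_mm_elbow[i], wide$z_mm_elbow[i]),
        c(wide$x_mm_wrist[i], wide$y_mm_wrist[i], wide$z_mm_wrist[i])
      ),
      reachstart_error_degenerate_geometry = function(e) NA_real_
    )
  }
  angles <- vapply(seq_len(nrow(wide)), angle_one, numeric(1))
  n_degenerate <- sum(is.na(angles))
  if (all(is.na(angles))) {
    stop_reach("all frames have degenerate elbow geometry.",
               "reachstart_error_insufficient_data")
  }
  imax <- which.max(angles)
  structure(
    list(max_angle = angles[imax],
         frame_of_max = wide$frame[imax],
         angles = tibble(frame = wide$frame, angle_deg = angles),
         n_degenerate_frames = n_degenerate),
    class = "elbow_angle_result"
  )
}

#' @export
print.elbow_angle_result <- function(x, ...) {
  cat(sprintf("Maximum elbow angle: %.2f deg (frame %s)\n",
              x$max_angle, format(x$frame_of_max)))
  if (x$n_degenerate_frames > 0) {
    cat(sprintf("  %d degenerate frame(s) skipped\n", x$n_degenerate_frames))
  }
  invisible(x)
}
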
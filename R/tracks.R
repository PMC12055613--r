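#' Keypoint and 3D pose track containers
#'
#' `keypoint_track()` builds a tidy per-frame, per-landmark table of 2D pixel
#' coordinates with tracking confidence, the in-memory form of a markerless
#' tracking export (one row per frame x landmark). `pose3d_track()` is the 3D
#' analogue in millimetres, as produced by a depth-camera body tracker.
#'
#' Both are tibbles carrying the acquisition frame rate as an attribute
#' (retrieved with [frame_rate()]). A 2D track must contain at least the
#' landmarks `wrist`, `elbow`, `shoulder` and `nape`; a 3D track at least
#' `shoulder`, `elbow` and `wrist`. At least two frames are required.
#'
#' @param data A data frame with columns `frame`, `landmark`, and either
#'   `x`, `y`, `likelihood` (2D, pixels; likelihood in \[0, 1\]) or
#'   `x_mm`, `y_mm`, `z_mm` (3D, millimetres).
#' @param frame_rate Acquisition frame rate in Hz.
#' @return A tibble of class `keypoint_track` or `pose3d_track`.
#' @examples
#' tr <- keypoint_track(
#'   tidyr::crossing(frame = 1:2, landmark = c("wrist", "elbow", "shoulder", "nape")) |>
#'     dplyr::mutate(x = dplyr::row_number() * 10, y = 0, likelihood = 1),
#'   frame_rate = 15
#' )
#' frame_rate(tr)
#' @export
keypoint_track <- function(data, frame_rate = 15) {
  data <- as_tibble(data)
  need <- c("frame", "landmark", "x", "y", "likelihood")
  if (!all(need %in% names(data))) {
    stop_reach(paste0("keypoint track needs columns: ",
                      paste(setdiff(need, names(data)), collapse = ", ")),
               "reachstart_error_format")
  }
  required <- c("wrist", "elbow", "shoulder", "nape")
  missing_lm <- setdiff(required, unique(data$landmark))
  if (length(missing_lm)) {
    stop_reach(paste0("missing required landmark(s): ",
                      paste(missing_lm, collapse = ", ")),
               "reachstart_error_format")
  }
  if (length(unique(data$frame)) < 2) {
    stop_reach("a keypoint track needs at least 2 frames.",
               "reachstart_error_format")
  }
  check_number(data$likelihood, "likelihood", 0, 1,
               class = "reachstart_error_format")
  check_number(frame_rate, "frame_rate", lower = 1e-9,
               class = "reachstart_error_format")
  new_track(data[c(need, setdiff(names(data), need))], frame_rate,
            "keypoint_track")
}

#' @rdname keypoint_track
#' @export
pose3d_track <- function(data, frame_rate = 30) {
  data <- as_tibble(data)
  need <- c("frame", "landmark", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(data))) {
    stop_reach(paste0("3D pose track needs columns: ",
                      paste(setdiff(need, names(data)), collapse = ", ")),
               "reachstart_error_format")
  }
  required <- c("shoulder", "elbow", "wrist")
  missing_lm <- setdiff(required, unique(data$landmark))
  if (length(missing_lm)) {
    stop_reach(paste0("missing required landmark(s): ",
                      paste(missing_lm, collapse = ", ")),
               "reachstart_error_format")
  }
  check_number(c(data$x_mm, data$y_mm, data$z_mm), "coordinates",
               class = "reachstart_error_format")
  check_number(frame_rate, "frame_rate", lower = 1e-9,
               class = "reachstart_error_format")
  new_track(data[c(need, setdiff(names(data), need))], frame_rate,
            "pose3d_track")
}

new_track <- function(data, frame_rate, cls) {
  structure(data,
            frame_rate = as.numeric(frame_rate),
            class = c(cls, class(tibble())))
}

#' Acquisition frame rate of a track
#'
#' @param x A [keypoint_track()] or [pose3d_track()].
#' @return Frame rate in Hz.
#' @export
frame_rate <- function(x) {
  fr <- attr(x, "frame_rate", exact = TRUE)
  if (is.null(fr)) stop_reach("object carries no frame_rate attribute.",
                              "reachstart_error_format")
  fr
}

track_landmarks <- function(x) unique(x$landmark)
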
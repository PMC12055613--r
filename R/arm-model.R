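#' Articulated two-segment arm model
#'
#' Geometric ground truth for a reaching movement: a rigid upper arm and
#' forearm hinged at the elbow, with the shoulder free to translate (trunk
#' lean). The arm moves in the subject's sagittal plane; the upper-arm
#' orientation and the interior elbow angle are specified per frame, so the
#' wrist path follows from forward kinematics. Segment lengths are constant
#' across frames by construction, which is what makes the Index of Elbow
#' Extension well defined on projections of this model.
#'
#' @param upper_arm_length,forearm_length Segment lengths in metres (> 0).
#' @param elbow_angle Per-frame interior elbow angle in degrees, each in
#'   \[0, 180\]; 180 is full extension (shoulder, elbow, wrist collinear),
#'   0 folds the wrist back onto the upper arm.
#' @param shoulder_azimuth Per-frame upper-arm orientation in degrees,
#'   measured in the sagittal plane from the downward vertical (0 = arm
#'   hanging, 90 = upper arm horizontal, pointing forward). Recycled to the
#'   number of frames if scalar. The default 30 reflects a seated reach to
#'   an object at table height, where the upper arm stays fairly low and
#'   most of the movement is elbow extension.
#' @param shoulder_position Shoulder position in metres: either a length-3
#'   vector (static shoulder) or an `n_frames` x 3 matrix (translating
#'   shoulder, e.g. trunk lean).
#' @return A list of class `arm_model`.
#' @seealso [simulate_reach()]
#' @examples
#' arm <- arm_model(elbow_angle = seq(60, 170, length.out = 30))
#' @export
arm_model <- function(upper_arm_length = 0.30,
                      forearm_length = 0.28,
                      elbow_angle = seq(60, 170, length.out = 30),
                      shoulder_azimuth = 30,
                      shoulder_position = c(0, 0, 0)) {
  check_number(upper_arm_length, "upper_arm_length", lower = 1e-12)
  check_number(forearm_length, "forearm_length", lower = 1e-12)
  if (upper_arm_length <= 0 || forearm_length <= 0) {
    stop_reach("segment lengths must be positive.",
               "reachstart_error_invalid_model")
  }
  check_number(elbow_angle, "elbow_angle", 0, 180)
  n <- length(elbow_angle)
  if (n < 2) {
    stop_reach("elbow_angle must cover at least 2 frames.",
               "reachstart_error_invalid_model")
  }
  if (length(shoulder_azimuth) == 1) shoulder_azimuth <- rep(shoulder_azimuth, n)
  check_number(shoulder_azimuth, "shoulder_azimuth")
  if (length(shoulder_azimuth) != n) {
    stop_reach("shoulder_azimuth must be scalar or one value per frame.",
               "reachstart_error_invalid_model")
  }
  if (is.null(dim(shoulder_position))) {
    shoulder_position <- matrix(shoulder_position, nrow = n, ncol = 3,
                                byrow = TRUE)
  }
  shoulder_position <- as.matrix(shoulder_position)
  if (nrow(shoulder_position) != n || ncol(shoulder_position) != 3) {
    stop_reach("shoulder_position must be length 3 or an n_frames x 3 matrix.",
               "reachstart_error_invalid_model")
  }
  check_number(c(shoulder_position), "shoulder_position")
  structure(
    list(upper_arm_length = upper_arm_length,
         forearm_length = forearm_length,
         elbow_angle = elbow_angle,
         shoulder_azimuth = shoulder_azimuth,
         shoulder_position = shoulder_position,
         n_frames = n),
    class = "arm_model"
  )
}

#' Orthographic camera model for 2D keypoint capture
#'
#' Emulates a fixed side-view webcam. Projection is orthographic: the image
#' keeps the vertical axis and the horizontal in-plane axis of a camera whose
#' optical axis sits at `azimuth` degrees from the normal of the subject's
#' sagittal plane. At azimuth 0 the camera views the sagittal plane square-on
#' and in-plane distances are preserved (up to `pixels_per_meter`); a nonzero
#' azimuth foreshortens the anterior axis by `cos(azimuth)`, affecting every
#' limb segment by the same factor — the distortion the IoEE normalisation is
#' designed to cancel.
#'
#' @param azimuth Camera azimuth in degrees.
#' @param pixels_per_meter Image scale (> 0).
#' @param jitter_sd Tracking noise SD, in pixels, added independently to each
#'   projected coordinate (>= 0).
#' @param frame_rate Capture rate in Hz.
#' @param principal_point Pixel offset `c(cx, cy)` of the world origin.
#' @return A list of class `camera_model`.
#' @export
camera_model <- function(azimuth = 0, pixels_per_meter = 1000, jitter_sd = 0,
                         frame_rate = 15, principal_point = c(640, 360)) {
  check_number(azimuth, "azimuth")
  check_number(pixels_per_meter, "pixels_per_meter", lower = 1e-12)
  check_number(jitter_sd, "jitter_sd", lower = 0)
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  check_number(principal_point, "principal_point")
  structure(
    list(azimuth = azimuth, pixels_per_meter = pixels_per_meter,
         jitter_sd = jitter_sd, frame_rate = frame_rate,
         principal_point = principal_point),
    class = "camera_model"
  )
}

# Forward kinematics: world coordinates (metres) of the four landmarks.
# World frame: x anterior, y medial (out of the sagittal plane), z up.
arm_world_coords <- function(arm) {
  phi <- deg2rad(arm$shoulder_azimuth)     # upper arm, from downward vertical
  theta <- deg2rad(arm$elbow_angle)        # interior elbow angle
  # in-plane (x, z) angle of the upper-arm direction, measured from +x axis
  gamma_u <- atan2(-cos(phi), sin(phi))
  # forearm direction: interior angle theta between elbow->shoulder and
  # elbow->wrist; theta = 180 deg continues the upper-arm line
  gamma_w <- gamma_u + pi - theta
  s <- arm$shoulder_position
  d_u <- cbind(cos(gamma_u), 0, sin(gamma_u))
  d_w <- cbind(cos(gamma_w), 0, sin(gamma_w))
  e <- s + arm$upper_arm_length * d_u
  w <- e + arm$forearm_length * d_w
  nape <- s + matrix(c(-0.08, 0.06, 0.15), nrow = arm$n_frames, ncol = 3,
                     byrow = TRUE)
  list(shoulder = s, elbow = e, wrist = w, nape = nape)
}

#' Simulate a reaching movement seen by a 2D camera and a 3D tracker
#'
#' Runs the forward kinematics of an [arm_model()] and returns the paired
#' observations of the same movement: a 2D [keypoint_track()] (orthographic
#' projection through a [camera_model()], with optional Gaussian pixel jitter)
#' and a noiseless 3D [pose3d_track()] in millimetres. With `jitter_sd = 0`
#' the 3D inter-landmark distances equal the model segment lengths at every
#' frame, and the elbow angle recomputed from the 3D track reproduces the
#' input profile.
#'
#' @param arm An [arm_model()].
#' @param camera A [camera_model()].
#' @param seed Integer seed for the jitter noise, or `NULL`.
#' @return A list with elements `track2d` (keypoint_track), `track3d`
#'   (pose3d_track) and `truth` (the generating arm model).
#' @examples
#' reach <- simulate_reach(arm_model(), camera_model(jitter_sd = 1), seed = 1)
#' compute_ioee(reach$track2d)
#' @export
simulate_reach <- function(arm, camera = camera_model(), seed = NULL) {
  if (!inherits(arm, "arm_model")) {
    stop_reach("`arm` must be an arm_model().", "reachstart_error_invalid_model")
  }
  if (!inherits(camera, "camera_model")) {
    stop_reach("`camera` must be a camera_model().",
               "reachstart_error_invalid_model")
  }
  coords <- arm_world_coords(arm)
  n <- arm$n_frames
  lms <- names(coords)

  world <- purrr::map_dfr(lms, function(lm) {
    m <- coords[[lm]]
    tibble(frame = seq_len(n), landmark = lm,
           wx = m[, 1], wy = m[, 2], wz = m[, 3])
  })

  track3d <- pose3d_track(
    dplyr::transmute(world, .data$frame, .data$landmark,
                     x_mm = .data$wx * 1000, y_mm = .data$wy * 1000,
                     z_mm = .data$wz * 1000),
    frame_rate = camera$frame_rate
  )

  a <- deg2rad(camera$azimuth)
  ppm <- camera$pixels_per_meter
  px <- ppm * (world$wx * cos(a) - world$wy * sin(a)) + camera$principal_point[1]
  # image convention: origin top-left, y grows downward
  py <- camera$principal_point[2] - ppm * world$wz
  if (camera$jitter_sd > 0) {
    noise <- with_seed_or_not(seed, rnorm(2 * length(px), 0, camera$jitter_sd))
    px <- px + noise[seq_along(px)]
    py <- py + noise[length(px) + seq_along(py)]
  }
  track2d <- keypoint_track(
    tibble(frame = world$frame, landmark = world$landmark,
           x = px, y = py, likelihood = 1),
    frame_rate = camera$frame_rate
  )
  list(track2d = track2d, track3d = track3d, truth = arm)
}
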
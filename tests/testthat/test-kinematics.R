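test_that("distance_series computes per-frame Euclidean distances and masks low-confidence frames", {
  tr <- make_track2d(shoulder = c(0, 0), elbow = c(1, 1), wrist = c(3, 4))
  ds <- distance_series(tr, "shoulder", "wrist")
  expect_equal(ds$distance, rep(5, 2)) # static 3-4-5 triangle
  expect_true(all(ds$valid))

  # confidence below threshold masks the frame without dropping the value
  tr2 <- make_track2d(shoulder = rbind(c(0, 0), c(0, 0)),
                      elbow = rbind(c(1, 0), c(1, 0)),
                      wrist = rbind(c(3, 4), c(6, 8)),
                      likelihood = list(shoulder = c(1, 1), elbow = c(1, 1),
                                        wrist = c(0.1, 1), nape = c(1, 1)))
  ds2 <- distance_series(tr2, "shoulder", "wrist", confidence_threshold = 0.6)
  expect_equal(ds2$valid, c(FALSE, TRUE))
  expect_equal(ds2$distance, c(5, 10))

  expect_reach_error(distance_series(tr, "shoulder", "hip"),
                     "reachstart_error_lookup")
})

test_that("distance_series matches a brute-force per-frame computation on a random track", {
  set.seed(41)
  n <- 10
  sh <- matrix(runif(2 * n, 0, 500), n)
  wr <- matrix(runif(2 * n, 0, 500), n)
  tr <- make_track2d(shoulder = sh, elbow = sh + 50, wrist = wr)
  ds <- distance_series(tr, "shoulder", "wrist")
  manual <- vapply(seq_len(n),
                   function(i) sqrt(sum((sh[i, ] - wr[i, ])^2)), 0)
  expect_equal(ds$distance, manual)
})

test_that("IoEE is 1 for a static fully extended arm and 0 for wrist at shoulder", {
  collinear <- make_track2d(shoulder = rbind(c(0, 0), c(0, 0)),
                            elbow = rbind(c(100, 0), c(100, 0)),
                            wrist = rbind(c(200, 0), c(200, 0)))
  res <- compute_ioee(collinear)
  expect_equal(res$ioee, 1.0)
  expect_false(res$exceeds_unity_flag)

  folded <- make_track2d(shoulder = rbind(c(0, 0), c(0, 0)),
                         elbow = rbind(c(100, 0), c(100, 0)),
                         wrist = rbind(c(0, 0), c(0, 0)))
  expect_equal(compute_ioee(folded)$ioee, 0.0)
})

test_that("IoEE equals the law-of-cosines chord ratio on a two-frame flexing arm", {
  f1 <- arm_frame_2d(90); f2 <- arm_frame_2d(120)
  tr <- make_track2d(shoulder = rbind(f1$shoulder, f2$shoulder),
                     elbow = rbind(f1$elbow, f2$elbow),
                     wrist = rbind(f1$wrist, f2$wrist))
  res <- compute_ioee(tr)
  # maximum shoulder-wrist chord occurs at the larger interior angle
  expect_equal(res$ioee, chord_length(120, 100, 80) / 180, tolerance = 1e-12)
  expect_equal(res$max_shoulder_elbow, 100, tolerance = 1e-9)
  expect_equal(res$max_elbow_wrist, 80, tolerance = 1e-9)
})

test_that("IoEE maxima are taken independently per distance pair over that pair's valid frames", {
  # wrist confidence kills frame 2 for wrist pairs but shoulder-elbow still
  # uses both frames
  f1 <- arm_frame_2d(90); f2 <- arm_frame_2d(150)
  tr <- make_track2d(shoulder = rbind(f1$shoulder, f2$shoulder),
                     elbow = rbind(f1$elbow, f2$elbow),
                     wrist = rbind(f1$wrist, f2$wrist),
                     likelihood = list(shoulder = c(1, 1), elbow = c(1, 1),
                                       wrist = c(1, 0.2), nape = c(1, 1)))
  res <- compute_ioee(tr, confidence_threshold = 0.5)
  expect_equal(res$max_shoulder_wrist, chord_length(90, 100, 80),
               tolerance = 1e-9)
  expect_equal(res$n_valid_frames, 1L)

  # no valid frames at all for a wrist pair -> insufficient data, pair named
  tr_bad <- make_track2d(shoulder = rbind(f1$shoulder, f2$shoulder),
                         elbow = rbind(f1$elbow, f2$elbow),
                         wrist = rbind(f1$wrist, f2$wrist),
                         likelihood = list(shoulder = c(1, 1),
                                           elbow = c(1, 1),
                                           wrist = c(0, 0), nape = c(1, 1)))
  err <- tryCatch(compute_ioee(tr_bad, confidence_threshold = 0.5),
                  error = identity)
  expect_s3_class(err, "reachstart_error_insufficient_data")
  expect_match(conditionMessage(err), "wrist")
})

test_that("IoEE is invariant to scaling, translation and rotation of pixel coordinates", {
  set.seed(7)
  reach <- simulate_reach(arm_model(elbow_angle = seq(70, 160,
                                                      length.out = 12)),
                          camera_model(jitter_sd = 2), seed = 5)
  tr <- reach$track2d
  base <- compute_ioee(tr)$ioee
  for (s in c(0.01, 3.7)) {
    scaled <- keypoint_track(
      dplyr::mutate(tibble::as_tibble(tr), x = x * s, y = y * s),
      frame_rate = frame_rate(tr))
    expect_equal(compute_ioee(scaled)$ioee, base, tolerance = 1e-12)
  }
  a <- 0.7
  moved <- keypoint_track(
    dplyr::mutate(tibble::as_tibble(tr),
                  xr = cos(a) * x - sin(a) * y + 123,
                  yr = sin(a) * x + cos(a) * y - 45,
                  x = xr, y = yr, xr = NULL, yr = NULL),
    frame_rate = frame_rate(tr))
  expect_equal(compute_ioee(moved)$ioee, base, tolerance = 1e-9)
})

test_that("IoEE respects the triangle bound for rigid arms and flags values above 1", {
  # rigid segments: bounded by 1 for any elbow angle profile
  set.seed(13)
  for (i in 1:5) {
    angles <- runif(20, 0, 180)
    reach <- simulate_reach(arm_model(elbow_angle = angles), camera_model())
    expect_lte(compute_ioee(reach$track2d)$ioee, 1 + 1e-12)
  }
  # per-pair confidence masking can break the bound: the extended frame is
  # valid for shoulder-wrist but its elbow dropped out, so the denominator
  # maxima come from a flexed frame only; raw value reported and flagged
  tr <- make_track2d(shoulder = rbind(c(0, 0), c(0, 0)),
                     elbow = rbind(c(100, 0), c(50, 0)),
                     wrist = rbind(c(200, 0), c(20, 0)),
                     likelihood = list(shoulder = c(1, 1),
                                       elbow = c(0.1, 1),
                                       wrist = c(1, 1), nape = c(1, 1)))
  res <- compute_ioee(tr, confidence_threshold = 0.5)
  expect_equal(res$ioee, 200 / (50 + 30))
  expect_true(res$exceeds_unity_flag)
})

test_that("elbow_angle_frame matches the dot-product oracle and handles degeneracy", {
  expect_equal(elbow_angle_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  expect_equal(elbow_angle_frame(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 90)
  expect_equal(elbow_angle_frame(c(0, 0, 0), c(1, 0, 0), c(1.5, 0.866, 0)),
               120, tolerance = 1e-3)
  set.seed(21)
  for (i in 1:20) {
    s <- rnorm(3); e <- rnorm(3); w <- rnorm(3)
    u <- s - e; v <- w - e
    oracle <- acos(pmin(1, pmax(-1, sum(u * v) /
                                  sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    expect_equal(elbow_angle_frame(s, e, w), oracle, tolerance = 1e-9)
  }
  expect_reach_error(elbow_angle_frame(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                     "reachstart_error_degenerate_geometry")
})

test_that("max_elbow_angle finds the per-frame maximum and skips degenerate frames", {
  reach <- simulate_reach(arm_model(elbow_angle = seq(60, 170,
                                                      length.out = 30)),
                          camera_model())
  res <- max_elbow_angle(reach$track3d)
  expect_equal(res$max_angle, 170, tolerance = 0.01)
  expect_equal(res$frame_of_max, 30)
  expect_equal(nrow(tidy(res)), 30)

  # brute-force per-frame oracle on a noisy 100-frame track
  set.seed(3)
  n <- 100
  df <- tidyr::crossing(frame = 1:n,
                        landmark = c("shoulder", "elbow", "wrist"))
  df <- dplyr::mutate(df, x_mm = rnorm(nrow(df), 0, 100),
                      y_mm = rnorm(nrow(df), 0, 100),
                      z_mm = rnorm(nrow(df), 0, 100))
  trk <- pose3d_track(df, frame_rate = 30)
  res2 <- max_elbow_angle(trk)
  wide <- tidyr::pivot_wider(df, names_from = landmark,
                             values_from = c(x_mm, y_mm, z_mm))
  oracle <- max(vapply(seq_len(n), function(i) {
    elbow_angle_frame(
      unlist(wide[i, c("x_mm_shoulder", "y_mm_shoulder", "z_mm_shoulder")]),
      unlist(wide[i, c("x_mm_elbow", "y_mm_elbow", "z_mm_elbow")]),
      unlist(wide[i, c("x_mm_wrist", "y_mm_wrist", "z_mm_wrist")]))
  }, 0))
  expect_equal(res2$max_angle, oracle, tolerance = 1e-9)

  # single-frame degenerate geometry in one frame is skipped and counted
  df2 <- tibble::tibble(
    frame = rep(1:2, each = 3),
    landmark = rep(c("shoulder", "elbow", "wrist"), 2),
    x_mm = c(0, 1, 1, 0, 0, 1), y_mm = c(0, 0, 1, 0, 0, 0),
    z_mm = 0)
  res3 <- max_elbow_angle(pose3d_track(df2, frame_rate = 30))
  expect_equal(res3$n_degenerate_frames, 1L)
  expect_equal(res3$max_angle, 90)
})
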
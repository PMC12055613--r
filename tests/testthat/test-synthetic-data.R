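test_that("simulate_reach preserves segment lengths and elbow-angle profile in 3D", {
  arm <- arm_model(upper_arm_length = 0.31, forearm_length = 0.26,
                   elbow_angle = seq(60, 170, length.out = 30))
  reach <- simulate_reach(arm, camera_model(jitter_sd = 0))
  wide <- tidyr::pivot_wider(reach$track3d, names_from = landmark,
                             values_from = c(x_mm, y_mm, z_mm))
  d <- function(a, b) sqrt((wide[[paste0("x_mm_", a)]] -
                              wide[[paste0("x_mm_", b)]])^2 +
                           (wide[[paste0("y_mm_", a)]] -
                              wide[[paste0("y_mm_", b)]])^2 +
                           (wide[[paste0("z_mm_", a)]] -
                              wide[[paste0("z_mm_", b)]])^2)
  expect_equal(d("shoulder", "elbow"), rep(310, 30), tolerance = 1e-9)
  expect_equal(d("elbow", "wrist"), rep(260, 30), tolerance = 1e-9)

  # recomputed per-frame elbow angles reproduce the input profile
  angles <- tidy(max_elbow_angle(reach$track3d))$angle_deg
  expect_equal(angles, arm$elbow_angle, tolerance = 0.01)
})

test_that("a permanently extended arm projects to collinear 2D landmarks", {
  arm <- arm_model(elbow_angle = rep(180, 5),
                   shoulder_azimuth = seq(20, 100, length.out = 5))
  reach <- simulate_reach(arm, camera_model(azimuth = 25, jitter_sd = 0))
  sw <- distance_series(reach$track2d, "shoulder", "wrist")$distance
  se <- distance_series(reach$track2d, "shoulder", "elbow")$distance
  ew <- distance_series(reach$track2d, "elbow", "wrist")$distance
  expect_equal(sw, se + ew, tolerance = 1e-9)
})

test_that("camera azimuth foreshortens in-plane components uniformly; IoEE survives projection", {
  # table-top reach: elbow extends while the upper arm stays near the
  # vertical, so every segment's foreshortening is nearly uniform — the
  # regime in which the dimensionless index cancels camera-angle distortion
  arm <- arm_model(elbow_angle = seq(60, 170, length.out = 30),
                   shoulder_azimuth = seq(20, 30, length.out = 30))
  straight <- simulate_reach(arm, camera_model(azimuth = 0, jitter_sd = 0))
  oblique <- simulate_reach(arm, camera_model(azimuth = 30, jitter_sd = 0))

  # anterior (image-x) extents shrink by cos(30), vertical extents unchanged
  for (lm in c("wrist", "elbow")) {
    x0 <- dplyr::filter(straight$track2d, landmark == lm)$x
    x30 <- dplyr::filter(oblique$track2d, landmark == lm)$x
    y0 <- dplyr::filter(straight$track2d, landmark == lm)$y
    y30 <- dplyr::filter(oblique$track2d, landmark == lm)$y
    expect_equal(diff(range(x30)), diff(range(x0)) * cos(pi / 6),
                 tolerance = 1e-9)
    expect_equal(y30, y0, tolerance = 1e-9)
  }

  # the dimensionless index agrees with the 3D law-of-cosines value
  ioee_2d <- compute_ioee(oblique$track2d)$ioee
  ioee_3d <- max(chord_length(arm$elbow_angle, 0.30, 0.28)) / (0.30 + 0.28)
  expect_equal(ioee_2d, ioee_3d, tolerance = 0.02)
})

test_that("simulate_reach is seed-deterministic and jitter varies across seeds", {
  arm <- arm_model()
  cam <- camera_model(jitter_sd = 2)
  r1 <- simulate_reach(arm, cam, seed = 11)
  r2 <- simulate_reach(arm, cam, seed = 11)
  r3 <- simulate_reach(arm, cam, seed = 12)
  expect_identical(r1$track2d, r2$track2d)
  expect_false(isTRUE(all.equal(r1$track2d$x, r3$track2d$x)))
  # 3D side is noiseless regardless of jitter
  expect_identical(r1$track3d, r3$track3d)
})

test_that("arm and camera models reject invalid parameters", {
  expect_reach_error(arm_model(upper_arm_length = 0),
                     "reachstart_error_invalid_model")
  expect_reach_error(arm_model(elbow_angle = c(50, 190)),
                     "reachstart_error_invalid_model")
  expect_reach_error(arm_model(elbow_angle = c(-1, 90)),
                     "reachstart_error_invalid_model")
  expect_reach_error(camera_model(jitter_sd = -1),
                     "reachstart_error_invalid_model")
  expect_reach_error(camera_model(pixels_per_meter = 0),
                     "reachstart_error_invalid_model")
})

test_that("simulate_emg_trial places the burst exactly at the injected onset", {
  tr <- simulate_emg_trial("VRT", true_onset = 750, burst_amplitude = 1,
                           baseline_sd = 0, seed = 4)
  nz <- which(tr$voltage_mV != 0)
  onset_idx <- floor(750 * 5000 / 1000) + 1
  expect_equal(nz[1], onset_idx)
  expect_equal(attr(tr, "true_onset_ms"), 750)

  expect_reach_error(simulate_emg_trial("VRT", true_onset = 400,
                                        cue_time = 500),
                     "reachstart_error_invalid_trial")
  expect_reach_error(simulate_emg_trial("VRT", true_onset = 1490,
                                        burst_duration = 150,
                                        trial_duration = 1500),
                     "reachstart_error_invalid_trial")
})

test_that("detect_onset recovers injected onsets on seeded trials and stays silent without a burst", {
  for (s in 1:20) {
    tr <- simulate_emg_trial("VART", true_onset = 700 + 10 * s,
                             burst_amplitude = 0.5, baseline_sd = 0.01,
                             seed = s)
    lat <- detect_onset(tr)$latency_ms
    expect_equal(lat, 200 + 10 * s, tolerance = 2)
  }
  silent <- simulate_emg_trial("VART", true_onset = 800,
                               burst_amplitude = 0, baseline_sd = 0.01,
                               seed = 1)
  expect_true(is.na(detect_onset(silent)$latency_ms))
})

test_that("simulate_trialset honors counts, ordering of means and the truncation window", {
  ts <- simulate_trialset(latency_model(), n_per_condition = 20, seed = 8,
                          baseline_sd = 0)
  expect_equal(nrow(ts), 60)
  expect_equal(as.integer(table(ts$condition)[c("VRT", "VART", "VSRT")]),
               rep(20L, 3))

  # zero-variance model reproduces the generating means exactly
  lm0 <- latency_model(sds = c(VRT = 0, VART = 0, VSRT = 0))
  ts0 <- simulate_trialset(lm0, n_per_condition = 20, seed = 3,
                           baseline_sd = 0)
  summ <- summarize_conditions(ts0)
  expect_equal(summ$conditions$mean_ms[summ$conditions$condition == "VRT"],
               326, tolerance = 0.2 + 1e-9)
  expect_equal(summ$startreact_ms, 49, tolerance = 0.4 + 1e-9)

  # ground-truth latency means recover the generating parameters (large n)
  big <- simulate_trialset(latency_model(), n_per_condition = 400, seed = 5,
                           burst_amplitude = 0) # no waveforms needed here
  means <- tapply(big$true_latency_ms, big$condition, mean)
  expect_equal(unname(means["VRT"]), 326, tolerance = 12)
  expect_equal(unname(means["VART"]), 274, tolerance = 12)
  expect_equal(unname(means["VSRT"]), 225, tolerance = 12)
  expect_true(means["VSRT"] <= means["VART"] &&
                means["VART"] <= means["VRT"])

  expect_reach_error(
    simulate_trialset(latency_model(truncation = c(900, 100)),
                      n_per_condition = 2, seed = 1),
    "reachstart_error_invalid_model")
})

test_that("trialset generation is seed-deterministic", {
  a <- simulate_trialset(latency_model(), n_per_condition = 4, seed = 42)
  b <- simulate_trialset(latency_model(), n_per_condition = 4, seed = 42)
  c <- simulate_trialset(latency_model(), n_per_condition = 4, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$true_latency_ms, c$true_latency_ms))
})

test_that("simulate_cohort builds a structurally valid table tied to one latent severity", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 15, seed = 2))
  expect_equal(nrow(coh), 15)
  expect_equal(coh$arat_total,
               coh$arat_grasp + coh$arat_grip + coh$arat_pinch +
                 coh$arat_gross)
  expect_true(all(coh$arat_grasp >= 0 & coh$arat_grasp <= 18))
  expect_true(all(coh$arat_grip >= 0 & coh$arat_grip <= 12))
  expect_true(all(coh$arat_pinch >= 0 & coh$arat_pinch <= 18))
  expect_true(all(coh$arat_gross >= 0 & coh$arat_gross <= 9))
  expect_true(all(coh$ioee >= 0 & coh$ioee <= 1))
  expect_true(all(coh$mas %in% 0:4))
  expect_equal(coh$startreact, coh$vart_mean - coh$vsrt_mean)
  expect_equal(coh$grip_normalized,
               100 * coh$grip_affected / coh$grip_less_affected)

  # deterministic monotone-opposite mapping: exact rank correlation -1
  spec0 <- cohort_spec(n_subjects = 12, ioee_sd = 0, startreact_sd = 0,
                       rt_sd = 0, arat_sd = 0, mas_sd = 0, grip_sd = 0,
                       seed = 9)
  coh0 <- simulate_cohort(spec0)
  expect_equal(cor(coh0$ioee, coh0$startreact, method = "spearman"), -1)

  expect_reach_error(cohort_spec(n_subjects = 2),
                     "reachstart_error_invalid_spec")
  expect_reach_error(cohort_spec(ioee_sd = -0.1),
                     "reachstart_error_invalid_spec")
})

test_that("cohort generator hits its calibrated population correlation", {
  # single large draw: estimated Spearman near the -0.70 design point
  coh <- simulate_cohort(cohort_spec(n_subjects = 2000, seed = 31))
  rho <- cor(coh$ioee, coh$startreact, method = "spearman")
  expect_equal(rho, -0.70, tolerance = 0.05)
})
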
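grid_s <- generate_grid(5, default_layout)
events_s <- schedule_events(grid_s, 300, 30, seed = 5)

test_that("zero amplitude means zero detections and keypresses", {
  prof <- noiseless_profile(
    perception = list(color = c(A = 0, sigma_e = 20),
                      shape = c(A = 0.5, sigma_e = 20),
                      motion = c(A = 0.5, sigma_e = 20)))
  ses <- simulate_participant(grid_s, events_s, "color", prof,
                              default_layout, seed = 1, emit_gaze = FALSE)
  expect_false(any(ses$truth$detected))
  expect_equal(nrow(ses$keypresses), 0L)
})

test_that("perfect wide perception with no noise detects every event", {
  prof <- noiseless_profile(
    perception = list(color = c(A = 1, sigma_e = 1e6),
                      shape = c(A = 1, sigma_e = 1e6),
                      motion = c(A = 1, sigma_e = 1e6)))
  res <- run_session(grid_s, events_s, "shape",
                     study_config(layout = default_layout, profile = prof,
                                  grace_s = 5),
                     seed = 2)
  expect_true(all(res$session$truth$detected))
  # full pipeline detection rate 100 %
  expect_true(all(res$outcomes$detected))
})

test_that("simulation is bit-identical under a fixed seed", {
  prof <- participant_profile()
  a <- simulate_participant(grid_s, events_s, "motion", prof,
                            default_layout, seed = 9)
  b <- simulate_participant(grid_s, events_s, "motion", prof,
                            default_layout, seed = 9)
  expect_identical(a, b)
  c2 <- simulate_participant(grid_s, events_s, "motion", prof,
                             default_layout, seed = 10)
  expect_false(identical(a$gaze, c2$gaze))
})

test_that("ground-truth ordering invariants hold", {
  prof <- participant_profile()
  ses <- simulate_participant(grid_s, events_s, "motion", prof,
                              default_layout, seed = 3, emit_gaze = FALSE)
  tr <- ses$truth
  expect_true(all(is.na(tr$keypress_s) == !tr$detected))
  d <- tr[tr$detected, ]
  expect_true(all(d$keypress_s >= d$gaze_arrival_s))
  expect_true(all(d$gaze_arrival_s >= d$onset_s))
})

test_that("noiseless gaze rests exactly on the center or a target feature", {
  prof <- noiseless_profile()
  ses <- simulate_participant(grid_s, events_s, "motion", prof,
                              default_layout, seed = 4)
  cx <- default_layout$screen_px[1] + (1920 - 1) / 2
  cy <- (1200 - 1) / 2
  at_center <- ses$gaze$gx == cx & ses$gaze$gy == cy
  at_feature <- paste(ses$gaze$gx, ses$gaze$gy) %in%
    paste(grid_s$gx, grid_s$gy)
  expect_true(all(at_center | at_feature))
})

test_that("Monte-Carlo detection fraction matches the Bernoulli model", {
  # oracle: conditional on the recorded onset eccentricities, the expected
  # number of detections is sum(p(e_i)); compare the pooled empirical count
  # against its 99 % normal envelope over 200 seeded simulations
  prof <- participant_profile()
  A <- prof$perception$motion["A"]; sig <- prof$perception$motion["sigma_e"]
  tot_det <- 0; mu <- 0; varsum <- 0
  for (s in 1:200) {
    ses <- simulate_participant(grid_s, events_s, "motion", prof,
                                default_layout, seed = 2000 + s,
                                emit_gaze = FALSE)
    p <- perception_prob(ses$truth$ecc_onset_deg, A, sig)
    tot_det <- tot_det + sum(ses$truth$detected)
    mu <- mu + sum(p); varsum <- varsum + sum(p * (1 - p))
  }
  expect_lt(abs(tot_det - mu), 2.576 * sqrt(varsum))
})

test_that("calibration simulation meets its closed-form error laws", {
  # zero noise -> exactly zero error, 21 reference records
  calib0 <- simulate_calibration(default_layout, noiseless_profile(),
                                 seed = 1)
  expect_equal(length(unique(calib0$point_id)), 21L)
  err0 <- calibration_error(calib0, default_layout)
  expect_equal(max(err0$err_x_deg, err0$err_y_deg), 0)

  # isotropic sigma: mean absolute per-axis deviation = sigma * sqrt(2/pi)
  sig <- 2
  prof <- participant_profile(noise_sd_deg = matrix(sig, 3, 2))
  errs <- vapply(1:500, function(s) {
    cal <- simulate_calibration(default_layout, prof, seed = 3000 + s,
                                n_samples = 5L)
    e <- calibration_error(cal, default_layout)
    unlist(e[e$screen == "all", c("err_x_deg", "err_y_deg")])
  }, numeric(2))
  expected <- sig * sqrt(2 / pi)
  expect_equal(mean(errs[1, ]), expected, tolerance = 0.02)
  expect_equal(mean(errs[2, ]), expected, tolerance = 0.02)
})

test_that("events on occluded features and bad inputs are rejected", {
  g2 <- generate_grid(5, default_layout)  # default mask occludes center-low
  bad <- data.frame(event_id = 0L, change_type = "color",
                    feature_id = g2$feature_id[!g2$visible][1],
                    onset_s = 1, offset_s = 2.5)
  expect_error(simulate_participant(g2, bad, "color",
                                    participant_profile(), default_layout,
                                    seed = 1), "occluded")
  expect_error(simulate_participant(g2, events_s, "texture",
                                    participant_profile(), default_layout,
                                    seed = 1), "instructed_type")
  expect_error(simulate_calibration(default_layout, participant_profile(),
                                    reference_points = data.frame()), "non-empty")
})
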
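test_that("constant and degenerate traces yield no contacts", {
  expect_equal(detect_initial_contacts(rep(5, 1000), 200), numeric(0))
  expect_error(detect_initial_contacts(numeric(0), 200), "empty")
  expect_equal(detect_initial_contacts(c(1, 2), 200), numeric(0))
})

test_that("noise-free synthetic traces are segmented at ground truth", {
  rec <- quick_subject(duration = 10, stride_rate = 1, seed = 2)
  contacts <- detect_initial_contacts(rec$imu_angle, rec$imu_rate)
  gt <- rec$ground_truth$contacts
  expect_length(contacts, 10)
  expect_length(gt, 10)
  expect_true(all(abs(contacts - gt) <= 1 / rec$imu_rate + 1e-9))
})

test_that("a subject configured at 105 strides per 3 min yields 105 contacts", {
  rec <- generate_subject(gait_model(105 / 180, 0, duration = 180),
                          artifacts = artifact_model(0, 0, 0, 0),
                          seed = 5, background_sd = 0)
  ev <- segment_gait(rec$imu_angle, rec$imu_rate)
  expect_equal(ev$n_contacts, 105)
  expect_equal(length(rec$ground_truth$contacts), 105)
})

test_that("stance/swing split finds the in-cycle minimum", {
  rec <- quick_subject(duration = 20, stride_rate = 1, seed = 3)
  ev <- segment_gait(rec$imu_angle, rec$imu_rate)
  frac <- (ev$stance_ends - ev$contacts[-length(ev$contacts)]) /
    diff(ev$contacts)
  expect_true(all(abs(frac - 0.60) <= 1 / rec$imu_rate + 1e-9))

  # symmetric sinusoid: minimum at 50% of the cycle
  rate <- 200
  t <- (0:(rate * 6 - 1)) / rate
  x <- cos(2 * pi * t)
  contacts <- detect_initial_contacts(x, rate, prominence = 1)
  ends <- split_stance_swing(x, contacts, rate)
  frac <- (ends - contacts[-length(contacts)]) / diff(contacts)
  expect_true(all(abs(frac - 0.5) < 0.01))

  # V-shaped cycle: boundary at the turning point
  v <- c(seq(10, 0, length.out = 101), seq(0.1, 10, length.out = 100))
  ends <- split_stance_swing(v, c(0, 1), 200)
  expect_equal(ends, 100 / 200)
})

test_that("segmentation tolerates stride variability and angle noise", {
  # counts stay exact under 10% stride CV and 1 degree of angle noise;
  # matched-filter refinement keeps interior contact timing within a few
  # samples (the waveform's peak curvature bounds what any estimator can
  # do at this noise level; sub-sample timing needs near-noise-free input)
  for (seed in 1:3) {
    rec <- generate_subject(gait_model(0.9, stride_cv = 0.1, duration = 40),
                            seed = seed, angle_noise_sd = 1,
                            background_sd = 0)
    ev <- segment_gait(rec$imu_angle, rec$imu_rate, smooth_window = 5)
    gt <- rec$ground_truth$contacts
    # a stride straddling the record boundary may count on either side
    expect_lte(abs(ev$n_contacts - length(gt)), 1)
    err <- vapply(ev$contacts, function(tc) min(abs(gt - tc)), 0)
    interior <- 2:(length(err) - 1)
    expect_lte(max(err[interior]), 0.025)
    expect_lte(max(err), 0.06)
  }
})

test_that("cycle validation flags duration outliers", {
  contacts <- c(0, 1, 2, 3, 5, 6)       # 4th cycle twice the median
  stance <- contacts[-length(contacts)] + 0.6 * diff(contacts)
  ev <- gait_events(contacts, stance)
  expect_equal(ev$cycle_valid, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(ev$stride_count, 4)
  ev_all <- gait_events(contacts, stance, policy = "none")
  expect_true(all(ev_all$cycle_valid))
  expect_error(gait_events(1.5, numeric(0)), "full cycle")
})

test_that("events map to half-open non-overlapping EEG ranges", {
  ev <- gait_events(c(0, 1, 2), c(0.6, 1.6))
  idx <- events_to_eeg_indices(ev, 512)
  # contact at 1.0 s = 0-based sample 512; half-open [0,512) then [512,1024)
  expect_equal(unname(idx[, "start"]), c(1L, 513L))
  expect_equal(unname(idx[, "end"]), c(513L, 1025L))
  expect_equal(unname(idx[1, "end"]), unname(idx[2, "start"]))

  rec <- quick_subject(duration = 20, stride_rate = 1, seed = 4)
  ev <- segment_gait(rec$imu_angle, rec$imu_rate)
  idx <- events_to_eeg_indices(ev, rec$eeg_rate, ncol(rec$eeg))
  expect_equal(nrow(idx), ev$stride_count)
  expect_true(all(idx[-1, "start"] >= idx[-nrow(idx), "end"]))
  expect_error(events_to_eeg_indices(ev, rec$eeg_rate, n_samples = 100),
               "outside")
})

test_that("stance and swing partition each cycle exactly", {
  rec <- quick_subject(duration = 20, stride_rate = 1, seed = 5)
  ev <- segment_gait(rec$imu_angle, rec$imu_rate)
  stance_dur <- ev$stance_ends - ev$contacts[-length(ev$contacts)]
  swing_dur <- ev$contacts[-1] - ev$stance_ends
  expect_equal(stance_dur + swing_dur, diff(ev$contacts))
  pct <- 100 * stance_dur / diff(ev$contacts) +
    100 * swing_dur / diff(ev$contacts)
  expect_equal(pct, rep(100, length(pct)))
})
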
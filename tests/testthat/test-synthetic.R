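test_that("model constructors validate their parameters", {
  expect_error(gait_model(0), "stride_rate")
  expect_error(gait_model(1, duration = 0), "duration")
  expect_error(gait_model(1, stance_fraction = 1.2))
  expect_error(artifact_model(emg_band = c(5, 80)))
  expect_error(effect_spec(electrodes = "XX", phase_window = c(3, 8),
                           amplitude_delta = 1,
                           affected_cells = "TsSC"), "XX")
  expect_error(effect_spec(affected_cells = "banana"), "banana")
})

test_that("a 68-stride 3-min configuration yields 68 ground-truth contacts", {
  rec <- generate_subject(gait_model(68 / 180, 0, duration = 180),
                          artifacts = artifact_model(0, 0, 0, 0),
                          seed = 1, background_sd = 0)
  expect_equal(length(rec$ground_truth$contacts), 68)
  expect_equal(nrow(rec$eeg), 32)
  expect_equal(rec$eeg_rate, 512)
  expect_equal(rec$imu_rate, 200)
  expect_equal(ncol(rec$eeg), 180 * 512)
  expect_equal(length(rec$imu_angle), 180 * 200)
})

test_that("zero artifacts and zero effect leave only the gait-locked component", {
  rec <- generate_subject(gait_model(1, 0, duration = 20),
                          artifacts = artifact_model(0, 0, 0, 0),
                          seed = 2, background_sd = 0)
  # EEG = topography x template only: Fp1 is a scaled copy of Cz
  ratio <- rec$eeg["Fp1", ] / rec$eeg["Cz", ]
  ratio <- ratio[is.finite(ratio)]
  expect_lt(diff(range(ratio)), 1e-9)
  # no blink transients: frontal deflections stay far below blink scale
  expect_lt(max(abs(rec$eeg["Fp1", ])), 50)
  # with background noise but no artifacts, still no blink-size deflections
  rec2 <- generate_subject(gait_model(1, 0, duration = 20),
                           artifacts = artifact_model(0, 0, 0, 0),
                           seed = 2, background_sd = 2)
  expect_lt(max(abs(rec2$eeg["Fp1", ])), 50)
})

test_that("generation is bit-identical under a fixed seed", {
  g <- gait_model(1, 0.05, duration = 10)
  r1 <- generate_subject(g, seed = 9)
  r2 <- generate_subject(g, seed = 9)
  expect_identical(r1$eeg, r2$eeg)
  expect_identical(r1$imu_angle, r2$imu_angle)
  r3 <- generate_subject(g, seed = 10)
  expect_false(identical(r1$eeg, r3$eeg))
})

test_that("with zero stride variability all cycles are identical", {
  rec <- generate_subject(gait_model(1, 0, duration = 30),
                          artifacts = artifact_model(0, 0, 0, 0),
                          seed = 3, background_sd = 0)
  expect_true(all(abs(diff(rec$ground_truth$cycle_durations)) < 1e-12))
  ev <- segment_gait(rec$imu_angle, rec$imu_rate)
  idx <- events_to_eeg_indices(ev, rec$eeg_rate, ncol(rec$eeg))
  traces <- lapply(extract_cycles(rec$eeg, idx), normalize_cycle)
  ref <- traces[[2]]
  for (tr in traces[3:(length(traces) - 1)]) {
    expect_lt(max(abs(tr - ref)), 1e-6)
  }
})

test_that("cohort layout and stride models follow the design", {
  ch <- generate_cohort(n_per_group = 12, seed = 7)
  expect_equal(nrow(ch$manifest), 48)
  expect_equal(length(unique(ch$manifest$subject_id)), 24)
  expect_equal(sum(ch$manifest$group == "T"), 24)  # 12 subjects x 2 cond

  # SC strides are metronome-locked (SD <= 2), sSC dispersed and group-split
  sc <- ch$manifest$strides_3min[ch$manifest$condition == "SC"]
  ssc_T <- ch$manifest$strides_3min[ch$manifest$condition == "sSC" &
                                      ch$manifest$group == "T"]
  ssc_O <- ch$manifest$strides_3min[ch$manifest$condition == "sSC" &
                                      ch$manifest$group == "O"]
  expect_lte(sd(sc), 2)
  expect_gt(sd(ssc_T), 5)
  expect_gt(mean(ssc_T), mean(ssc_O))

  expect_error(generate_cohort(n_per_group = 1), "at least 2")
})

test_that("effects land only in the affected cells", {
  eff <- effect_spec("Fz", c(3, 8), amplitude_delta = 5,
                     factor = "interaction", affected_cells = "TsSC")
  base <- list(duration = 12, background_sd = 0,
               artifacts = artifact_model(0, 0, 0, 0))
  g <- gait_model(1, 0, duration = 12)
  hit <- generate_subject(g, artifacts = base$artifacts, effect = eff,
                          cell = "TsSC", seed = 5, background_sd = 0)
  miss <- generate_subject(g, artifacts = base$artifacts, effect = eff,
                           cell = "TSC", seed = 5, background_sd = 0)
  null_rec <- generate_subject(g, artifacts = base$artifacts,
                               effect = null_effect(), cell = "TsSC",
                               seed = 5, background_sd = 0)
  expect_true(hit$ground_truth$effect_applied)
  expect_false(miss$ground_truth$effect_applied)
  expect_identical(miss$eeg, null_rec$eeg)
  dfz <- hit$eeg["Fz", ] - miss$eeg["Fz", ]
  expect_gt(max(dfz), 4.9)                        # bump peaks at delta
  expect_identical(hit$eeg["Oz", ], miss$eeg["Oz", ])  # other electrodes
})

test_that("cohort recordings rematerialize deterministically", {
  ch <- generate_cohort(n_per_group = 2, seed = 3, duration = 8)
  r1 <- materialize_recording(ch, 1)
  r2 <- materialize_recording(ch, 1)
  expect_identical(r1$eeg, r2$eeg)
  ch_m <- generate_cohort(n_per_group = 2, seed = 3, duration = 8,
                          materialize = TRUE)
  expect_length(ch_m$recordings, 8)
  expect_identical(ch_m$recordings[[1]]$eeg, r1$eeg)
})

test_that("matrix-level simulation injects the effect on the per-cycle scale", {
  eff <- effect_spec("Fz", c(3, 8), amplitude_delta = 0.75,
                     factor = "interaction", affected_cells = "TsSC")
  simn <- simulate_matrix_cohort(6, null_effect(), seed = 5)
  sime <- simulate_matrix_cohort(6, eff, seed = 5)
  d <- sime$data[["Fz"]] - simn$data[["Fz"]]
  # T-group sSC traces (subjects 1-6, condition 1) carry the bump
  # (raised-cosine peak 0.75 lands between phase grid points)
  expect_gt(max(d[1:6, 1, ]), 0.6)
  # O-group and SC traces identical
  expect_equal(max(abs(d[7:12, , ])), 0)
  expect_equal(max(abs(d[, 2, ])), 0)
  # bump confined to the 3-8% window
  expect_equal(max(abs(d[1:6, 1, 10:100])), 0)
})
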
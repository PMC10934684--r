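# Synthetic walking-EEG generator.
#
# Emulates the acquisition geometry of a mobile gait-EEG session: 32-channel
# scalp EEG at 512 Hz and a right-thigh flexion angle at 200 Hz sharing one
# clock, for 2 groups (O overground / T treadmill) x 2 speed-control
# conditions (sSC self-selected / SC metronome). A stereotyped gait-locked
# delta waveform is embedded at fronto-central electrodes, time-warped to
# each stride; ocular, glossokinetic and muscle artifact sources are mixed
# in with anatomically plausible scalp topographies; background activity is
# 1/f-shaped Gaussian noise. Ground truth (contact times, embedded template,
# source time courses) rides along for testing every downstream stage.

#' Gait timing model for a synthetic subject
#'
#' @param stride_rate strides per second (cadence / 2); e.g. 68 strides in
#'   3 min is `68/180`
#' @param stride_cv coefficient of variation of stride duration (0 = fully
#'   periodic, metronome-like)
#' @param stance_fraction fraction of the cycle spent in stance, in (0, 1).
#'   Default 0.60, the conventional stance share of the gait cycle.
#' @param duration length of the walk in seconds (3-min protocol = 180)
#' @return object of class `gait_model`
#' @export
gait_model <- function(stride_rate, stride_cv = 0, stance_fraction = 0.6,
                       duration = 180) {
  stopifnot(stride_rate > 0, stride_cv >= 0,
            stance_fraction > 0, stance_fraction < 1)
  if (duration <= 0) stop("duration must be positive")
  structure(list(stride_rate = stride_rate, stride_cv = stride_cv,
                 stance_fraction = stance_fraction, duration = duration),
            class = "gait_model")
}

#' Artifact source model
#'
#' Amplitudes are scalp-level microvolts at the most-affected electrode.
#'
#' @param ocular_rate blink rate, blinks/second
#' @param ocular_amp blink amplitude at Fp electrodes, microvolts
#' @param glossokinetic_amp tongue-artifact amplitude, microvolts
#' @param emg_amp neck/temporalis EMG amplitude, microvolts
#' @param emg_band EMG frequency band, Hz (within (13, 100))
#' @return object of class `artifact_model`
#' @export
artifact_model <- function(ocular_rate = 0.25, ocular_amp = 100,
                           glossokinetic_amp = 30, emg_amp = 15,
                           emg_band = c(20, 80)) {
  stopifnot(ocular_rate >= 0, ocular_amp >= 0, glossokinetic_amp >= 0,
            emg_amp >= 0, length(emg_band) == 2,
            emg_band[1] > 13, emg_band[2] < 100, emg_band[1] < emg_band[2])
  structure(list(ocular_rate = ocular_rate, ocular_amp = ocular_amp,
                 glossokinetic_amp = glossokinetic_amp, emg_amp = emg_amp,
                 emg_band = emg_band),
            class = "artifact_model")
}

#' Ground-truth group x condition effect specification
#'
#' Describes an amplitude modulation injected into the gait-locked delta
#' component: which electrodes, which window of the gait cycle (percent),
#' how many microvolts, and which design cells receive it.
#'
#' @param electrodes montage labels receiving the effect
#' @param phase_window `c(start, end)` in percent of the gait cycle
#' @param amplitude_delta microvolts added at the window peak (0 = null)
#' @param factor which design factor the effect represents:
#'   `"group"`, `"condition"` or `"interaction"`
#' @param affected_cells subset of `c("OsSC","OSC","TsSC","TSC")`
#' @return object of class `effect_spec`
#' @export
effect_spec <- function(electrodes = character(), phase_window = c(0, 0),
                        amplitude_delta = 0,
                        factor = c("interaction", "group", "condition"),
                        affected_cells = character()) {
  factor <- match.arg(factor)
  stopifnot(length(phase_window) == 2, phase_window[1] >= 0,
            phase_window[2] <= 100, amplitude_delta >= 0)
  if (amplitude_delta > 0) stopifnot(phase_window[1] < phase_window[2])
  bad <- setdiff(electrodes, montage_info()$active_labels)
  if (length(bad) > 0) stop("effect electrodes not in montage: ",
                            paste(bad, collapse = ", "))
  bad_cells <- setdiff(affected_cells, c("OsSC", "OSC", "TsSC", "TSC"))
  if (length(bad_cells) > 0) stop("unknown cells: ",
                                  paste(bad_cells, collapse = ", "))
  structure(list(electrodes = electrodes, phase_window = phase_window,
                 amplitude_delta = amplitude_delta, factor = factor,
                 affected_cells = affected_cells),
            class = "effect_spec")
}

#' Null effect (no systematic cell differences)
#' @return an `effect_spec` with zero amplitude
#' @export
null_effect <- function() effect_spec()

# approximate 2D head-disc coordinates for the 32 recorded channels
# (x: left->right, y: posterior->anterior); used to build smooth scalp
# topographies for embedded sources
channel_positions <- function() {
  pos <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95), Fpz = c(0, 1.00),
    F3 = c(-0.55, 0.48), F4 = c(0.55, 0.48), F7 = c(-0.81, 0.59),
    F8 = c(0.81, 0.59), Fz = c(0, 0.50),
    FC1 = c(-0.33, 0.27), FC2 = c(0.33, 0.27), FC5 = c(-0.78, 0.30),
    FC6 = c(0.78, 0.30), C3 = c(-0.50, 0), C4 = c(0.50, 0), Cz = c(0, 0),
    T7 = c(-1.00, 0), T8 = c(1.00, 0),
    CP1 = c(-0.33, -0.27), CP2 = c(0.33, -0.27), CP5 = c(-0.78, -0.30),
    CP6 = c(0.78, -0.30), P3 = c(-0.55, -0.48), P4 = c(0.55, -0.48),
    P7 = c(-0.81, -0.59), P8 = c(0.81, -0.59), Pz = c(0, -0.50),
    POz = c(0, -0.72), O1 = c(-0.31, -0.95), O2 = c(0.31, -0.95),
    Oz = c(0, -1.00), M1 = c(-1.10, -0.30), M2 = c(1.10, -0.30)
  )
  colnames(pos) <- c("x", "y")
  pos[recorded_labels(), ]
}

# smooth Gaussian scalp profile centered at (cx, cy)
topo_gauss <- function(cx, cy, sigma = 0.45) {
  pos <- channel_positions()
  d2 <- (pos[, "x"] - cx)^2 + (pos[, "y"] - cy)^2
  exp(-d2 / (2 * sigma^2))
}

#' Stereotyped gait-locked delta waveform
#'
#' The per-cycle cortical template embedded by the generator, as a function
#' of gait phase: a fundamental plus a weaker second harmonic, so one
#' stride carries one dominant low-frequency oscillation (delta range for
#' stride durations near 1-3 s).
#'
#' @param phase gait phase in `[0, 1)`
#' @return template amplitude (unit peak scale)
#' @export
gait_template <- function(phase) {
  sin(2 * pi * phase) + 0.4 * sin(4 * pi * phase + 0.8)
}

# raised-cosine window over a percent-phase interval, peak 1 at its center
phase_bump <- function(phase, window_pct) {
  lo <- window_pct[1] / 100; hi <- window_pct[2] / 100
  inside <- phase >= lo & phase <= hi
  out <- numeric(length(phase))
  out[inside] <- 0.5 * (1 - cos(2 * pi * (phase[inside] - lo) / (hi - lo)))
  out
}

# 1/f-shaped Gaussian noise, unit variance, via spectral shaping
pink_noise <- function(n, rate) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- seq(0, rate, length.out = n + 1)[seq_len(n)]
  f[f > rate / 2] <- rate - f[f > rate / 2]  # mirror to physical frequency
  shape <- 1 / sqrt(pmax(f, 0.5))            # flat below 0.5 Hz
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# band-limited Gaussian noise, unit variance
band_noise <- function(n, band, rate) {
  flt <- signal::butter(4, band / (rate / 2), type = "pass")
  x <- filtfilt_zero_phase(flt$b, flt$a, stats::rnorm(n))
  as.numeric(scale(x))
}

# draw cycle durations and contact times covering [0, duration].
# The record starts at the minimum thigh angle (mid-swing) so the first
# contact is a prominent peak rather than an edge artifact.
draw_gait_timing <- function(gait) {
  base <- 1 / gait$stride_rate
  t0 <- (1 - gait$stance_fraction) * base
  n_max <- ceiling(gait$duration / base) + 5L
  dur <- base * (1 + gait$stride_cv * stats::rnorm(n_max))
  dur <- pmin(pmax(dur, 0.5 * base), 1.5 * base)
  contacts <- t0 + c(0, cumsum(dur))
  keep <- contacts <= gait$duration
  list(contacts = contacts[keep],
       durations = dur[seq_len(max(sum(keep) - 1L, 0L))],
       t0 = t0, base = base, all_contacts = contacts, all_durations = dur)
}

# thigh angle: per cycle a piecewise-cosine with its unique maximum at the
# contact (phase 0) and unique minimum at the stance->swing transition
thigh_angle_wave <- function(phase, stance_fraction, amp = 20, offset = 10) {
  sf <- stance_fraction
  out <- ifelse(phase < sf,
                amp * cos(pi * phase / sf),
                -amp * cos(pi * (phase - sf) / (1 - sf)))
  offset + out
}

# map times to (cycle index, within-cycle phase) given contact times that
# bracket every t (contacts extended virtually at both ends)
time_to_phase <- function(t, contacts, durations, t0, base) {
  ext_contacts <- c(t0 - base, contacts,
                    contacts[length(contacts)] +
                      base * seq_len(ceiling(max(0, max(t) -
                                                   contacts[length(contacts)]) / base) + 1L))
  ext_dur <- diff(ext_contacts)
  idx <- findInterval(t, ext_contacts, rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  idx[idx > length(ext_dur)] <- length(ext_dur)
  phase <- (t - ext_contacts[idx]) / ext_dur[idx]
  phase[phase < 0] <- 0
  phase[phase >= 1] <- 1 - 1e-12
  list(phase = phase, cycle = idx - 1L)  # cycle 1 = first real cycle
}

#' Generate one synthetic subject-condition recording
#'
#' Builds a synchronized EEG + IMU recording with known gait structure:
#' the thigh angle has exactly one flexion maximum per stride (the initial
#' contact) and one minimum (the stance-to-swing transition); a gait-locked
#' delta-band template is embedded at fronto-central electrodes, warped to
#' each cycle's duration; artifact sources (2 ocular, 1 glossokinetic,
#' 2 EMG) are mixed in with frontal / inferior-frontal / temporal
#' topographies; background is 1/f Gaussian noise. If `cell` is among
#' `effect$affected_cells`, the effect's amplitude bump is added to the
#' named electrodes inside the phase window of every cycle.
#'
#' @param gait a [gait_model()]
#' @param artifacts an [artifact_model()] (all-zero amplitudes give
#'   artifact-free data)
#' @param effect an [effect_spec()]
#' @param cell design cell of this recording: `"OsSC"`, `"OSC"`, `"TsSC"`
#'   or `"TSC"`
#' @param seed integer; fixes all randomness (same seed = bit-identical
#'   output)
#' @param eeg_rate,imu_rate sampling rates, Hz
#' @param background_sd background-noise SD per channel, microvolts
#' @param delta_amp scalp amplitude of the embedded gait-locked delta
#'   component at its peak electrode, microvolts
#' @param angle_noise_sd additive IMU angle noise SD, degrees
#' @return a [raw_recording()] whose `ground_truth` holds contact times,
#'   stance-end times, cycle durations, the embedded per-cycle template,
#'   source time courses and their topographies
#' @export
generate_subject <- function(gait, artifacts = artifact_model(),
                             effect = null_effect(),
                             cell = c("OsSC", "OSC", "TsSC", "TSC"),
                             seed = 1L, eeg_rate = 512, imu_rate = 200,
                             background_sd = 2, delta_amp = 4,
                             angle_noise_sd = 0) {
  cell <- match.arg(cell)
  stopifnot(inherits(gait, "gait_model"), inherits(artifacts, "artifact_model"),
            inherits(effect, "effect_spec"))
  group <- if (startsWith(cell, "O")) "O" else "T"
  condition <- if (grepl("sSC", cell)) "sSC" else "SC"

  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  timing <- draw_gait_timing(gait)
  contacts <- timing$contacts
  if (length(contacts) < 2) stop("duration too short for a single gait cycle")
  n_cycles <- length(contacts) - 1L
  stance_ends <- contacts[seq_len(n_cycles)] +
    gait$stance_fraction * timing$durations

  n_eeg <- round(gait$duration * eeg_rate)
  n_imu <- round(gait$duration * imu_rate)
  t_eeg <- (seq_len(n_eeg) - 1) / eeg_rate
  t_imu <- (seq_len(n_imu) - 1) / imu_rate

  ph_imu <- time_to_phase(t_imu, contacts, timing$durations, timing$t0,
                          timing$base)
  angle <- thigh_angle_wave(ph_imu$phase, gait$stance_fraction)
  if (angle_noise_sd > 0) angle <- angle + angle_noise_sd * stats::rnorm(n_imu)

  labels <- recorded_labels()
  n_ch <- length(labels)

  # --- sources and topographies ------------------------------------------
  ph_eeg <- time_to_phase(t_eeg, contacts, timing$durations, timing$t0,
                          timing$base)
  src_delta <- gait_template(ph_eeg$phase)

  # blink train
  src_blink <- numeric(n_eeg)
  if (artifacts$ocular_rate > 0 && artifacts$ocular_amp > 0) {
    n_blinks <- max(1L, stats::rpois(1, artifacts$ocular_rate * gait$duration))
    centers <- sort(stats::runif(n_blinks, 0.5, gait$duration - 0.5))
    for (tc in centers) {
      src_blink <- src_blink + exp(-(t_eeg - tc)^2 / (2 * 0.08^2))
    }
  }
  # slow horizontal eye movements: smoothed random telegraph
  src_heog <- numeric(n_eeg)
  if (artifacts$ocular_amp > 0) {
    n_flips <- max(2L, stats::rpois(1, 0.5 * gait$duration))
    flips <- sort(stats::runif(n_flips, 0, gait$duration))
    lev <- cumsum(c(sample(c(-1, 1), 1),
                    2 * (stats::rbinom(n_flips, 1, 0.5)) - 1))[-1]
    step <- lev[pmin(findInterval(t_eeg, flips) + 1L, length(lev))]
    flt <- signal::butter(2, 1 / (eeg_rate / 2), type = "low")
    src_heog <- filtfilt_zero_phase(flt$b, flt$a, step)
  }
  src_gloss <- if (artifacts$glossokinetic_amp > 0)
    band_noise(n_eeg, c(0.5, 2), eeg_rate) else numeric(n_eeg)
  src_emg_l <- if (artifacts$emg_amp > 0)
    band_noise(n_eeg, artifacts$emg_band, eeg_rate) else numeric(n_eeg)
  src_emg_r <- if (artifacts$emg_amp > 0)
    band_noise(n_eeg, artifacts$emg_band, eeg_rate) else numeric(n_eeg)

  unit_max <- function(w) w / max(w)
  topo <- cbind(
    delta = delta_amp * unit_max(topo_gauss(0, 0.30, 0.50)),
    blink = artifacts$ocular_amp * unit_max(topo_gauss(0, 1.05, 0.35)),
    heog = 0.4 * artifacts$ocular_amp *
      (topo_gauss(-0.55, 0.85, 0.35) - topo_gauss(0.55, 0.85, 0.35)),
    gloss = artifacts$glossokinetic_amp *
      unit_max(topo_gauss(-0.90, 0.45, 0.40) + topo_gauss(0.90, 0.45, 0.40) +
                 0.6 * topo_gauss(0, 1.0, 0.45)),
    emg_l = artifacts$emg_amp * unit_max(topo_gauss(-1.0, 0, 0.30)),
    emg_r = artifacts$emg_amp * unit_max(topo_gauss(1.0, 0, 0.30))
  )
  rownames(topo) <- labels
  sources <- rbind(delta = src_delta, blink = src_blink, heog = src_heog,
                   gloss = src_gloss, emg_l = src_emg_l, emg_r = src_emg_r)

  eeg <- topo %*% sources
  if (background_sd > 0) {
    for (ch in seq_len(n_ch)) {
      eeg[ch, ] <- eeg[ch, ] + background_sd * pink_noise(n_eeg, eeg_rate)
    }
  }

  effect_applied <- effect$amplitude_delta > 0 && cell %in% effect$affected_cells
  if (effect_applied) {
    bump <- effect$amplitude_delta * phase_bump(ph_eeg$phase, effect$phase_window)
    rows <- match(effect$electrodes, labels)
    for (r in rows) eeg[r, ] <- eeg[r, ] + bump
  }

  rownames(eeg) <- labels
  raw_recording(
    eeg = eeg, imu_angle = angle, eeg_rate = eeg_rate, imu_rate = imu_rate,
    channel_labels = labels,
    subject_id = sprintf("SYN%04d", as.integer(seed) %% 10000L),
    group = group, condition = condition,
    ground_truth = list(
      contacts = contacts, stance_ends = stance_ends,
      cycle_durations = timing$durations, stride_count = n_cycles,
      template = gait_template(seq(0, 1, length.out = 101)[1:100]),
      sources = sources, topographies = topo,
      effect_applied = effect_applied, effect = effect, cell = cell,
      delta_amp = delta_amp, background_sd = background_sd
    )
  )
}

# Table-1-like stride-count models: sSC is dispersed and group-dependent,
# SC is metronome-locked near 68 strides / 3 min for both groups.
draw_strides_3min <- function(group, condition) {
  if (condition == "SC") {
    round(min(max(stats::rnorm(1, 68, 0.75), 65), 71))
  } else if (group == "T") {
    round(min(max(stats::rnorm(1, 116.7, 17.0), 60), 150))
  } else {
    round(min(max(stats::rnorm(1, 88.4, 16.0), 55), 130))
  }
}

#' Generate a full synthetic cohort design
#'
#' Lays out 2 groups x `n_per_group` subjects x 2 conditions, drawing each
#' recording's stride count from group/condition models mimicking the
#' 3-min walking protocol (sSC dispersed around the group mean, SC tight
#' around the 68-stride metronome rate), and assigns each recording a
#' deterministic sub-seed. Recordings themselves are materialized lazily
#' via [materialize_recording()] unless `materialize = TRUE`.
#'
#' @param n_per_group subjects per group (at least 2)
#' @param effect an [effect_spec()] shared by the cohort
#' @param seed cohort master seed
#' @param duration recording length in seconds (the cadence models always
#'   refer to strides per 3 min, so shorter recordings keep realistic
#'   stride rates)
#' @param stride_cv_sSC,stride_cv_SC within-recording stride-duration CV
#' @param materialize generate all recordings now (memory-heavy for full
#'   cohorts at 3 min)
#' @param ... further arguments passed to [generate_subject()]
#' @return object of class `cohort_dataset`: `manifest` data.frame
#'   (subject_id, group, condition, cell, strides_3min, stride_rate, seed),
#'   `effect`, `seed`, generator arguments, and `recordings` (list or NULL)
#' @export
generate_cohort <- function(n_per_group = 12, effect = null_effect(),
                            seed = 1L, duration = 180,
                            stride_cv_sSC = 0.05, stride_cv_SC = 0.02,
                            materialize = FALSE, ...) {
  if (n_per_group < 2) stop("n_per_group must be at least 2 (ANOVA undefined)")
  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  groups <- rep(c("T", "O"), each = n_per_group)
  subjects <- sprintf("S%02d", seq_len(2 * n_per_group))
  rows <- list()
  k <- 0L
  for (i in seq_along(subjects)) {
    for (cond in c("sSC", "SC")) {
      k <- k + 1L
      strides <- draw_strides_3min(groups[i], cond)
      rows[[k]] <- data.frame(
        subject_id = subjects[i], group = groups[i], condition = cond,
        cell = paste0(groups[i], cond), strides_3min = strides,
        stride_rate = strides / 180,
        stride_cv = if (cond == "SC") stride_cv_SC else stride_cv_sSC,
        seed = sample.int(.Machine$integer.max - 1L, 1L)
      )
    }
  }
  manifest <- do.call(rbind, rows)
  cohort <- structure(
    list(manifest = manifest, effect = effect, seed = as.integer(seed),
         duration = duration, subject_args = list(...), recordings = NULL),
    class = "cohort_dataset"
  )
  if (materialize) {
    cohort$recordings <- lapply(seq_len(nrow(manifest)), function(i)
      materialize_recording(cohort, i))
  }
  cohort
}

#' Materialize one recording of a cohort design
#'
#' Regenerates recording `i` of the cohort deterministically from its
#' manifest row (per-recording seed, stride model, shared effect).
#'
#' @param cohort a `cohort_dataset` from [generate_cohort()]
#' @param i manifest row index
#' @return a [raw_recording()]
#' @export
materialize_recording <- function(cohort, i) {
  row <- cohort$manifest[i, ]
  gait <- gait_model(stride_rate = row$stride_rate, stride_cv = row$stride_cv,
                     duration = cohort$duration)
  args <- c(list(gait = gait, effect = cohort$effect, cell = row$cell,
                 seed = row$seed), cohort$subject_args)
  rec <- do.call(generate_subject, args)
  rec$subject_id <- row$subject_id
  rec
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset: %d recordings (%d subjects x 2 conditions), %g s each, effect delta = %g uV\n",
              nrow(x$manifest), nrow(x$manifest) / 2, x$duration,
              x$effect$amplitude_delta))
  invisible(x)
}

# Gaussian-kernel smoothing of white noise, rescaled to unit SD; used for
# matrix-level simulation so phase-adjacent points are correlated the way
# cycle-averaged low-pass EEG is
smooth_unit_noise <- function(n, kernel_sd = 3) {
  half <- ceiling(3 * kernel_sd)
  k <- stats::dnorm(-half:half, sd = kernel_sd)
  x <- stats::rnorm(n + 2 * half)
  y <- stats::filter(x, k, sides = 2)[(half + 1):(half + n)]
  as.numeric(y) / sqrt(sum(k^2))
}

#' Simulate a cohort directly at the cycle-matrix level
#'
#' Generates subject x condition gait-phase traces for selected electrodes
#' at the *epoched* stage: each trace is the gait-locked template (scaled
#' by the electrode's topography weight and a subject-specific gain) plus
#' smooth noise whose SD is the per-cycle noise divided by the square root
#' of that recording's stride count — i.e., what ensemble averaging of that
#' many cycles leaves behind. Effects are injected as in
#' [generate_subject()], on the per-cycle amplitude scale. This is the
#' cheap route for large statistical simulations (type-I error, power);
#' the full recording route exercises the identical downstream statistics.
#'
#' @param n_per_group subjects per group
#' @param effect an [effect_spec()]
#' @param seed integer seed
#' @param electrodes electrode labels to simulate (default `"Fz"`)
#' @param n_points gait-phase points per trace (default 100)
#' @param cycle_noise_sd per-cycle noise SD, same (a.u.) scale as the
#'   template's unit peak
#' @param template_amp peak template amplitude, a.u.
#' @param subject_gain_sd between-subject SD of the template gain
#' @param condition_gain_sd within-subject (condition-level) gain SD
#' @return list with `data` (named list per electrode: array
#'   subjects x 2 conditions x n_points), `group` (per-subject factor
#'   vector), `n_cycles` (subjects x 2), `manifest`
#' @export
simulate_matrix_cohort <- function(n_per_group = 12, effect = null_effect(),
                                   seed = 1L, electrodes = "Fz",
                                   n_points = 100, cycle_noise_sd = 0.5,
                                   template_amp = 0.5,
                                   subject_gain_sd = 0.1,
                                   condition_gain_sd = 0.05) {
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  n_sub <- 2L * n_per_group
  groups <- rep(c("T", "O"), each = n_per_group)
  conds <- c("sSC", "SC")
  phase <- seq(0, 1, length.out = n_points + 1)[seq_len(n_points)]
  tmpl <- gait_template(phase)
  w <- topo_gauss(0, 0.30, 0.50)
  w <- w / max(w)

  data <- stats::setNames(
    lapply(electrodes, function(e) array(
      0, dim = c(n_sub, 2, n_points),
      dimnames = list(NULL, conds, NULL))),
    electrodes)
  n_cycles <- matrix(0L, n_sub, 2, dimnames = list(NULL, conds))
  gains <- stats::rnorm(n_sub, 1, subject_gain_sd)

  for (s in seq_len(n_sub)) {
    for (ci in 1:2) {
      strides <- draw_strides_3min(groups[s], conds[ci])
      n_cycles[s, ci] <- strides
      cell <- paste0(groups[s], conds[ci])
      hit <- effect$amplitude_delta > 0 && cell %in% effect$affected_cells
      g <- gains[s] * (1 + condition_gain_sd * stats::rnorm(1))
      for (e in electrodes) {
        tr <- g * template_amp * w[[e]] * tmpl +
          (cycle_noise_sd / sqrt(strides)) * smooth_unit_noise(n_points)
        if (hit && e %in% effect$electrodes) {
          tr <- tr + effect$amplitude_delta * phase_bump(phase, effect$phase_window)
        }
        data[[e]][s, ci, ] <- tr
      }
    }
  }
  list(data = data, group = groups, n_cycles = n_cycles,
       manifest = data.frame(subject_id = sprintf("S%02d", seq_len(n_sub)),
                             group = groups))
}
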
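# Gait-event detection from the right-thigh IMU angle.
#
# Initial contact = local maximum of the thigh flexion angle; each gait
# cycle spans two successive contacts and splits into stance and swing at
# the minimum thigh angle inside the cycle. Events detected on the 200 Hz
# IMU stream are mapped onto EEG sample indices through the shared marker
# clock (both streams start at marker time 0).

#' Detect initial contacts from the thigh angle
#'
#' Finds local maxima of the (already smoothed) thigh flexion angle with a
#' minimum prominence over the surrounding troughs and a minimum temporal
#' separation. Flat peaks resolve to the first sample of the plateau.
#'
#' @param angle thigh angle, degrees, sampled at `imu_rate`
#' @param imu_rate IMU sampling rate, Hz
#' @param min_period minimum stride period, seconds. The default 0.5 s
#'   is safe for the slow-walking protocols this pipeline targets
#'   (<= 0.8 m/s implies stride periods well above 1 s).
#' @param prominence minimum rise over surrounding minima, degrees
#' @param smooth_window optional moving-average pre-smoother width in
#'   samples (0 = none; angle traces from vendor pipelines arrive smoothed)
#' @param flip_sign set `TRUE` if the sensor's flexion convention is
#'   inverted (maxima become minima)
#' @param refine after argmax detection, refine each contact by
#'   cross-correlating its neighborhood against the cycle-averaged
#'   template (matched filtering; default `TRUE`). On noisy traces this
#'   recovers most of the timing precision a raw argmax loses; on clean
#'   periodic traces it is a no-op.
#' @return numeric vector of contact times in seconds (sample index /
#'   `imu_rate`, 0-based)
#' @export
detect_initial_contacts <- function(angle, imu_rate, min_period = 0.5,
                                    prominence = 5, smooth_window = 0,
                                    flip_sign = FALSE, refine = TRUE) {
  if (length(angle) == 0) stop("empty angle series")
  stopifnot(all(is.finite(angle)), imu_rate > 0)
  x <- as.numeric(angle)
  if (flip_sign) x <- -x
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(x, k, sides = 2)
    x[!is.na(sm)] <- sm[!is.na(sm)]
  }
  n <- length(x)
  if (n < 3) return(numeric(0))

  # strict local maxima with first-of-plateau tie-break: a peak starts a
  # run of equal values that rises on the left and falls after the run
  d <- diff(x)
  rises <- c(FALSE, d > 0)                  # x[i] > x[i-1]
  next_change <- function(i) {              # first non-zero diff at/after i
    while (i <= n - 1 && d[i] == 0) i <- i + 1
    if (i <= n - 1) d[i] else 0
  }
  cand <- which(rises)
  peaks <- cand[vapply(cand, function(i) i <= n && next_change(i) < 0, TRUE)]
  if (length(peaks) == 0) return(numeric(0))

  # enforce minimum separation greedily from the highest peak down, so
  # noise-induced maxima near a true peak never displace it
  min_gap <- round(min_period * imu_rate)
  peaks <- peaks[order(x[peaks], decreasing = TRUE)]
  accepted <- integer(0)
  for (p in peaks) {
    if (length(accepted) == 0 || all(abs(accepted - p) >= min_gap)) {
      accepted <- c(accepted, p)
    }
  }
  accepted <- sort(accepted)

  # walk-out prominence: on each side, the lowest point before a sample
  # higher than the peak (or the record edge) is the base
  # walk-out prominence. A peak whose flank is truncated by the record
  # edge is judged on the intact flank, but must additionally sit about
  # one stride from its neighbor (periodicity check), so noise bumps near
  # the edges are not promoted to contacts while genuine first/last
  # contacts with a clipped flank are kept.
  min_gap <- round(min_period * imu_rate)
  walkout <- function(p) {
    left <- p - 1; lmin <- x[p]
    while (left >= 1 && x[left] <= x[p]) { lmin <- min(lmin, x[left]); left <- left - 1 }
    right <- p + 1; rmin <- x[p]
    while (right <= n && x[right] <= x[p]) { rmin <- min(rmin, x[right]); right <- right + 1 }
    # a flank is "clipped" when its walk-out hit the record edge after
    # covering less than a minimum-stride span: too short to have reached
    # the cycle's trough
    c(lmin = lmin, rmin = rmin,
      lclip = (left < 1) && (p - 1 < min_gap),
      rclip = (right > n) && (n - p < min_gap))
  }
  wo <- vapply(accepted, walkout, numeric(4))
  full_ok <- accepted[x[accepted] - pmax(wo["lmin", ], wo["rmin", ]) >= prominence &
                        wo["lclip", ] == 0 & wo["rclip", ] == 0]
  edge_cand <- accepted[(wo["lclip", ] == 1 & wo["rclip", ] == 0 &
                           x[accepted] - wo["rmin", ] >= prominence) |
                          (wo["rclip", ] == 1 & wo["lclip", ] == 0 &
                             x[accepted] - wo["lmin", ] >= prominence)]
  peaks <- full_ok
  if (length(edge_cand) > 0 && length(full_ok) >= 2) {
    med <- stats::median(diff(full_ok))
    height_floor <- stats::median(x[full_ok]) - 2 * prominence
    for (p in edge_cand) {
      gap <- min(abs(p - full_ok))
      if (gap >= 0.6 * med && gap <= 1.4 * med && x[p] >= height_floor) {
        peaks <- sort(c(peaks, p))
      }
    }
  }
  if (refine && length(peaks) >= 3) {
    peaks <- refine_contacts(as.numeric(angle) * (if (flip_sign) -1 else 1),
                             peaks, imu_rate)
  }
  (peaks - 1) / imu_rate
}

# matched-filter timing refinement: build a phase-warped cycle template by
# averaging the (unsmoothed) angle around every detected peak — the left
# and right halves of each window scaled by that cycle's own preceding and
# following stride duration, so stride-to-stride duration variability does
# not smear the template — then shift each contact to the integer lag
# minimizing the squared mismatch. Edge peaks without a full window keep
# their argmax position.
refine_contacts <- function(x, peaks, imu_rate, half_frac = 0.45,
                            max_lag_frac = 0.06, n_iter = 2L) {
  n <- length(x)
  phi <- seq(-half_frac, half_frac, length.out = 163L)
  for (iter in seq_len(n_iter)) {
    m <- length(peaks)
    if (m < 3) return(peaks)
    period <- stats::median(diff(peaks))
    max_lag <- max(2L, round(max_lag_frac * period))
    dL <- c(period, diff(peaks))
    dR <- c(diff(peaks), period)
    seg <- function(i, l) {
      Ts <- ifelse(phi < 0, dL[i], dR[i])
      stats::approx(seq_len(n), x, xout = peaks[i] + l + phi * Ts,
                    rule = 2)$y
    }
    inside <- peaks - half_frac * dL - max_lag >= 1 &
      peaks + half_frac * dR + max_lag <= n
    if (sum(inside) < 2) return(peaks)
    tmpl <- rowMeans(vapply(which(inside), function(i) seg(i, 0),
                            numeric(length(phi))))
    peaks <- vapply(seq_len(m), function(i) {
      if (!inside[i]) return(peaks[i])
      sse <- vapply(-max_lag:max_lag, function(l)
        sum((seg(i, l) - tmpl)^2), 0)
      peaks[i] + (-max_lag:max_lag)[which.min(sse)]
    }, 0)
    peaks <- sort(unique(peaks))
  }
  peaks
}

#' Split each gait cycle into stance and swing
#'
#' The stance-to-swing boundary of cycle *i* is the time of the minimum
#' thigh angle strictly inside `(contact_i, contact_{i+1})`; flat minima
#' resolve to the first sample.
#'
#' @param angle thigh angle, degrees
#' @param contacts contact times from [detect_initial_contacts()]
#' @param imu_rate IMU sampling rate, Hz
#' @return numeric vector of stance-end times, one per cycle
#' @export
split_stance_swing <- function(angle, contacts, imu_rate) {
  if (length(contacts) < 2) stop("need at least 2 contacts")
  n_cyc <- length(contacts) - 1
  vapply(seq_len(n_cyc), function(i) {
    i0 <- floor(contacts[i] * imu_rate) + 2    # strictly after the contact
    i1 <- ceiling(contacts[i + 1] * imu_rate)  # up to (not incl.) next contact
    if (i1 - i0 < 1) stop("cycle ", i, " contains fewer than 3 samples")
    seg <- angle[i0:i1]
    (i0 + which.min(seg) - 2) / imu_rate
  }, 0)
}

#' Assemble and validate gait events
#'
#' Bundles contacts and stance boundaries into a `gait_events` object and
#' flags implausible cycles. The default policy invalidates cycles whose
#' duration falls outside `[0.5, 1.5]` times the median cycle duration;
#' policy `"none"` keeps everything.
#'
#' @param contacts contact times, seconds
#' @param stance_ends per-cycle stance-end times, seconds
#' @param policy `"duration"` (default) or `"none"`
#' @return object of class `gait_events` with `contacts`, `stance_ends`,
#'   `cycle_valid` (logical per cycle) and `stride_count` (valid cycles)
#' @export
gait_events <- function(contacts, stance_ends, policy = c("duration", "none")) {
  policy <- match.arg(policy)
  if (length(contacts) < 2) stop("need at least one full cycle")
  stopifnot(all(diff(contacts) > 0),
            length(stance_ends) == length(contacts) - 1,
            all(stance_ends > contacts[-length(contacts)]),
            all(stance_ends < contacts[-1]))
  dur <- diff(contacts)
  valid <- if (policy == "none") rep(TRUE, length(dur))
           else dur >= 0.5 * stats::median(dur) & dur <= 1.5 * stats::median(dur)
  structure(list(contacts = contacts, stance_ends = stance_ends,
                 cycle_valid = valid, stride_count = sum(valid),
                 n_contacts = length(contacts)),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("gait_events: %d contacts, %d valid cycles (of %d), mean stride %.3f s\n",
              length(x$contacts), x$stride_count, length(x$cycle_valid),
              mean(diff(x$contacts)[x$cycle_valid])))
  invisible(x)
}

#' Detect, split and validate gait events from an IMU trace
#'
#' Convenience wrapper: [detect_initial_contacts()] +
#' [split_stance_swing()] + [gait_events()].
#'
#' @inheritParams detect_initial_contacts
#' @param policy cycle-validation policy, see [gait_events()]
#' @return a `gait_events` object
#' @export
segment_gait <- function(angle, imu_rate, min_period = 0.5, prominence = 5,
                         smooth_window = 0, flip_sign = FALSE,
                         policy = "duration") {
  contacts <- detect_initial_contacts(angle, imu_rate, min_period, prominence,
                                      smooth_window, flip_sign)
  if (length(contacts) < 2) stop("fewer than 2 initial contacts detected")
  stance <- split_stance_swing(if (flip_sign) -angle else angle,
                               contacts, imu_rate)
  gait_events(contacts, stance, policy = policy)
}

#' Map gait cycles to EEG sample index ranges
#'
#' Converts valid cycles into half-open EEG sample ranges
#' `[start, end)` (1-based start, `end` exclusive) via the shared marker
#' clock: index = round(time x eeg_rate). Adjacent cycles share the
#' boundary sample exactly once (it belongs to the later cycle).
#'
#' @param events a `gait_events` object
#' @param eeg_rate EEG sampling rate, Hz
#' @param n_samples number of EEG samples in the record (range check)
#' @return integer matrix with columns `start`, `end` (half-open, 1-based),
#'   one row per *valid* cycle
#' @export
events_to_eeg_indices <- function(events, eeg_rate, n_samples = Inf) {
  edges <- round(events$contacts * eeg_rate)
  if (any(edges < 0) || any(edges > n_samples)) {
    stop("gait event outside the EEG record")
  }
  starts <- edges[-length(edges)] + 1L   # 1-based
  ends <- edges[-1] + 1L                 # exclusive
  m <- cbind(start = starts, end = ends)[events$cycle_valid, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}
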
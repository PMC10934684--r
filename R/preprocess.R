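# Band-specific Butterworth filtering around the ICA stage.
#
# Each analysis band uses a wide Butterworth band-pass (band-specific low
# edge up to 100 Hz) plus a 50 Hz notch *before* ICA — broadband input
# improves artifact separation — and a band-specific low-pass *after*
# component removal. All filters are 4th-order Butterworth designs applied
# forward-backward (zero phase), because gait-phase alignment cannot
# tolerate group delay.

#' Analysis-band filter definition
#'
#' @param name one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`
#' @param pre_band optional override of the pre-ICA band-pass corners (Hz)
#' @param post_lowpass optional override of the post-ICA low-pass cutoff (Hz)
#' @param order Butterworth design order (default 4)
#' @return object of class `band_definition`
#' @details Defaults per band: delta 0.5–100 Hz pre, 4 Hz post; theta
#'   4.5–100 / 7.5; alpha 8–100 / 12; beta 13–100 / 30.
#' @export
band_definition <- function(name = c("delta", "theta", "alpha", "beta"),
                            pre_band = NULL, post_lowpass = NULL, order = 4L) {
  name <- match.arg(name)
  defaults <- list(delta = list(pre = c(0.5, 100), post = 4),
                   theta = list(pre = c(4.5, 100), post = 7.5),
                   alpha = list(pre = c(8, 100), post = 12),
                   beta  = list(pre = c(13, 100), post = 30))
  d <- defaults[[name]]
  pre <- if (is.null(pre_band)) d$pre else pre_band
  post <- if (is.null(post_lowpass)) d$post else post_lowpass
  stopifnot(length(pre) == 2, pre[1] > 0, pre[1] < pre[2], post < pre[2],
            order >= 1)
  structure(list(name = name, pre_band = pre, post_lowpass = post,
                 order = as.integer(order)),
            class = "band_definition")
}

#' Power-line notch filter definition
#'
#' 4th-order Butterworth band-stop centered on the mains frequency.
#'
#' @param center center frequency, Hz (50 for European mains)
#' @param half_width half-width of the stop band, Hz
#' @param order design order
#' @return object of class `notch_spec`
#' @export
notch_spec <- function(center = 50, half_width = 1, order = 4L) {
  stopifnot(center > 0, half_width > 0, half_width < center)
  structure(list(center = center, half_width = half_width,
                 order = as.integer(order)),
            class = "notch_spec")
}

# steady-state initial filter state for a unit step input (the standard
# filtfilt startup trick): solve (I - A') zi = B for the DF2T companion form
lfilter_zi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1) return(numeric(0))
  A <- rbind(-a[-1], cbind(diag(1, n - 2), 0))
  B <- b[-1] - b[1] * a[-1]
  # (I - A') is near-singular for very low normalized cutoffs; least-squares
  # via QR keeps the startup state finite and accurate enough for padding
  M <- diag(1, n - 1) - t(A)
  as.numeric(qr.coef(qr(M, LAPACK = TRUE), B))
}

# zero-phase forward-backward filtering with odd-symmetric edge extension.
# pad: samples of extension on each side (default 3 x the polynomial length,
# enough given steady-state initialization).
filtfilt_zero_phase <- function(b, a, x, pad = 3L * (max(length(a), length(b)) - 1L)) {
  nx <- length(x)
  if (nx <= pad) stop("signal too short for zero-phase filtering (need > ",
                      pad, " samples)")
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[nx] - x[(nx - 1):(nx - pad)])
  y <- lfilter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- lfilter_cpp(b, a, y, zi * y[1])
  rev(y)[(pad + 1):(pad + nx)]
}

# design helpers returning list(b, a)
design_bandpass <- function(band, rate) {
  ny <- rate / 2
  if (band$pre_band[2] >= ny) stop("band edge ", band$pre_band[2],
                                   " Hz violates Nyquist (", ny, " Hz)")
  flt <- signal::butter(band$order, band$pre_band / ny, type = "pass")
  list(b = flt$b, a = flt$a)
}

design_notch <- function(notch, rate) {
  ny <- rate / 2
  edges <- c(notch$center - notch$half_width, notch$center + notch$half_width)
  if (edges[2] >= ny) stop("notch edge violates Nyquist")
  flt <- signal::butter(notch$order, edges / ny, type = "stop")
  list(b = flt$b, a = flt$a)
}

design_lowpass <- function(cutoff, order, rate) {
  ny <- rate / 2
  if (cutoff >= ny) stop("low-pass cutoff violates Nyquist")
  flt <- signal::butter(order, cutoff / ny, type = "low")
  list(b = flt$b, a = flt$a)
}

apply_rows <- function(eeg, fun) {
  out <- t(apply(eeg, 1, fun))
  dimnames(out) <- dimnames(eeg)
  out
}

#' Pre-ICA filtering: band-pass + mains notch
#'
#' Applies the band's wide Butterworth band-pass and the 50 Hz notch to
#' every channel, zero-phase (forward-backward, so the effective magnitude
#' response is the design's squared and the group delay is zero).
#'
#' @param eeg channels x samples matrix (or a numeric vector for one channel)
#' @param band a [band_definition()]
#' @param notch a [notch_spec()], or `NULL` to skip the notch
#' @param rate sampling rate, Hz
#' @param zero_phase apply forward-backward (default) or single-pass causal
#' @return filtered data, same shape as the input
#' @export
prefilter <- function(eeg, band = band_definition("delta"),
                      notch = notch_spec(), rate = 512, zero_phase = TRUE) {
  vec <- is.null(dim(eeg))
  if (vec) eeg <- matrix(eeg, nrow = 1)
  stopifnot(all(is.finite(eeg)), rate > 2 * band$pre_band[2])
  bp <- design_bandpass(band, rate)
  nt <- if (is.null(notch)) NULL else design_notch(notch, rate)
  run <- function(x) {
    y <- if (zero_phase) filtfilt_zero_phase(bp$b, bp$a, x)
         else lfilter_cpp(bp$b, bp$a, x, lfilter_zi(bp$b, bp$a) * x[1])
    if (!is.null(nt)) {
      y <- if (zero_phase) filtfilt_zero_phase(nt$b, nt$a, y)
           else lfilter_cpp(nt$b, nt$a, y, lfilter_zi(nt$b, nt$a) * y[1])
    }
    y
  }
  out <- apply_rows(eeg, run)
  if (vec) out[1, ] else out
}

#' Post-ICA band-limiting low-pass
#'
#' Zero-phase Butterworth low-pass at the band's analysis cutoff
#' (e.g. 4 Hz for delta), applied after artifact-component removal.
#'
#' @inheritParams prefilter
#' @return low-passed data, same shape as the input
#' @export
postfilter <- function(eeg, band = band_definition("delta"), rate = 512,
                       zero_phase = TRUE) {
  vec <- is.null(dim(eeg))
  if (vec) eeg <- matrix(eeg, nrow = 1)
  stopifnot(all(is.finite(eeg)))
  lp <- design_lowpass(band$post_lowpass, band$order, rate)
  run <- function(x) {
    if (zero_phase) filtfilt_zero_phase(lp$b, lp$a, x)
    else lfilter_cpp(lp$b, lp$a, x, lfilter_zi(lp$b, lp$a) * x[1])
  }
  out <- apply_rows(eeg, run)
  if (vec) out[1, ] else out
}

#' Magnitude response of a designed filter stage
#'
#' Evaluates |H(f)| of the designed transfer function at the requested
#' frequencies. For zero-phase (forward-backward) application the
#' effective gain is this magnitude squared.
#'
#' @param stage `"bandpass"`, `"notch"` or `"lowpass"`
#' @param f frequencies to evaluate, Hz
#' @param rate sampling rate, Hz
#' @param band a [band_definition()] (for bandpass/lowpass stages)
#' @param notch a [notch_spec()] (for the notch stage)
#' @return numeric vector |H(f)|, single-pass magnitude
#' @export
filter_gain <- function(stage = c("bandpass", "notch", "lowpass"), f,
                        rate = 512, band = band_definition("delta"),
                        notch = notch_spec()) {
  stage <- match.arg(stage)
  flt <- switch(stage,
                bandpass = design_bandpass(band, rate),
                notch = design_notch(notch, rate),
                lowpass = design_lowpass(band$post_lowpass, band$order, rate))
  w <- 2 * pi * f / rate
  H <- vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(flt$b) - 1))
    num <- sum(flt$b * z)
    z <- exp(-1i * wi * (seq_along(flt$a) - 1))
    Mod(num / sum(flt$a * z))
  }, 0)
  H
}
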
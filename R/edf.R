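# Minimal EDF (European Data Format, 16-bit) container support.
# Covers exactly what the pipeline needs: equal-rate multichannel signals in
# physical units, one continuous segment. Header fields are fixed-width
# ASCII per the format; samples are little-endian int16 with per-channel
# linear physical scaling, so round-trips are exact up to the per-channel
# quantization step (phys_range / 65535).

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = -width)  # left-justified, space-padded
}

fmt_num_field <- function(x, width = 8L) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= width) return(pad_field(s, width))
  }
  stop("cannot represent ", x, " in ", width, " characters")
}

#' Write a multichannel signal to an EDF file
#'
#' @param x numeric matrix, channels x samples, in physical units
#' @param rate sampling rate in Hz (shared by all channels)
#' @param labels channel labels (length `nrow(x)`)
#' @param path output file path
#' @param physical_dim physical unit string (e.g. `"uV"`)
#' @param start_time POSIXct recording start (default epoch origin; the
#'   pipeline synchronizes streams via markers, not wall-clock time)
#' @return `path`, invisibly
#' @export
write_edf <- function(x, rate, labels, path, physical_dim = "uV",
                      start_time = as.POSIXct("2000-01-01 00:00:00", tz = "UTC")) {
  stopifnot(is.matrix(x), is.numeric(x), all(is.finite(x)),
            length(labels) == nrow(x), rate > 0)
  ns <- nrow(x)
  nsamp <- ncol(x)
  # one data record spanning the whole signal keeps arbitrary durations exact
  duration <- nsamp / rate

  dig_min <- -32768; dig_max <- 32767
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  # use the values as they will be *stored* (8-char fields) for scaling,
  # so write->read reproduces samples to the quantization step
  pmin_s <- vapply(pmin, fmt_num_field, "")
  pmax_s <- vapply(pmax, fmt_num_field, "")
  pmin <- as.numeric(pmin_s); pmax <- as.numeric(pmax_s)
  pmin <- pmin(pmin, apply(x, 1, min))  # stored min must still bound the data
  pmax <- pmax(pmax, apply(x, 1, max))
  pmin_s <- vapply(pmin, fmt_num_field, ""); pmin <- as.numeric(pmin_s)
  pmax_s <- vapply(pmax, fmt_num_field, ""); pmax <- as.numeric(pmax_s)

  gain <- (pmax - pmin) / (dig_max - dig_min)
  dig <- round((x - pmin) / gain) + dig_min
  dig[dig < dig_min] <- dig_min; dig[dig > dig_max] <- dig_max
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad_field("0", 8))
  wr(pad_field("X", 80))                       # patient id (anonymized)
  wr(pad_field("gaitwave", 80))                # recording id
  wr(pad_field(format(start_time, "%d.%m.%y"), 8))
  wr(pad_field(format(start_time, "%H.%M.%S"), 8))
  wr(pad_field(as.character(256L + 256L * ns), 8))
  wr(pad_field("", 44))
  wr(pad_field("1", 8))                        # number of data records
  wr(fmt_num_field(duration, 8))
  wr(pad_field(as.character(ns), 4))
  wr(paste0(vapply(labels, pad_field, "", width = 16L), collapse = ""))
  wr(paste0(rep(pad_field("", 80), ns), collapse = ""))       # transducer
  wr(paste0(rep(pad_field(physical_dim, 8), ns), collapse = ""))
  wr(paste0(pmin_s, collapse = ""))
  wr(paste0(pmax_s, collapse = ""))
  wr(paste0(rep(pad_field(as.character(dig_min), 8), ns), collapse = ""))
  wr(paste0(rep(pad_field(as.character(dig_max), 8), ns), collapse = ""))
  wr(paste0(rep(pad_field("", 80), ns), collapse = ""))       # prefiltering
  wr(paste0(rep(pad_field(as.character(nsamp), 8), ns), collapse = ""))
  wr(paste0(rep(pad_field("", 32), ns), collapse = ""))
  # data record: all samples of signal 1, then signal 2, ...
  writeBin(as.integer(t(dig)[TRUE]), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file written for this pipeline
#'
#' Supports continuous equal-rate EDF recordings (possibly split into
#' several data records). Returns physical-unit samples.
#'
#' @param path EDF file path
#' @return list with `data` (channels x samples matrix, physical units),
#'   `labels`, `rate` (Hz), `physical_dim`
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rdnum <- function(n) as.numeric(trimws(rd(n)))
  rd(8)                        # version
  rd(80); rd(80); rd(8); rd(8) # ids, date, time
  rdnum(8)                     # header bytes
  rd(44)
  n_rec <- rdnum(8)
  duration <- rdnum(8)
  ns <- as.integer(rdnum(4))
  fields <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fields(16)
  fields(80)                   # transducer
  pdim <- fields(8)
  pmin <- as.numeric(fields(8)); pmax <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)                   # prefiltering
  spr <- as.integer(fields(8)) # samples per record per signal
  fields(32)
  if (length(unique(spr)) != 1L) stop("EDF with mixed per-signal rates not supported")
  total <- spr[1] * n_rec
  out <- matrix(0, nrow = ns, ncol = total)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- pmin[s] + (raw - dmin[s]) * (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
      out[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- phys
    }
  }
  list(data = out, labels = labels, rate = spr[1] / duration,
       physical_dim = pdim[1])
}

#' Per-channel EDF quantization step of a stored matrix
#'
#' The amplitude resolution a write/read round-trip is exact to:
#' physical range divided by the 16-bit digital range.
#'
#' @param x the matrix that was (or will be) written
#' @return numeric vector, one step per channel
#' @export
edf_quantization_step <- function(x) {
  rng <- apply(x, 1, function(r) diff(range(r)))
  rng[rng < .Machine$double.eps] <- 1
  rng / 65535
}
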
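# Per-cycle normalization and ensemble averaging.
#
# Every valid gait cycle is cut from the cleaned EEG, amplitude-normalized
# per electrode to that cycle's local peak (max |amplitude|), resampled to
# 100 evenly spaced gait-phase points on [0%, 100%) by linear
# interpolation, and ensemble-averaged: across cycles within a subject
# (30 x 100 cycle matrix), then across subjects within each group x
# condition cell (group map: mean and SD).

#' Cut per-cycle EEG segments
#'
#' @param eeg channels x samples matrix (cleaned, band-limited EEG)
#' @param index_ranges integer matrix from [events_to_eeg_indices()]:
#'   half-open `[start, end)` sample ranges, one row per valid cycle
#' @return list of channels x length segments
#' @export
extract_cycles <- function(eeg, index_ranges) {
  if (is.null(dim(index_ranges)) || nrow(index_ranges) == 0) return(list())
  stopifnot(ncol(index_ranges) == 2)
  if (any(index_ranges[, 1] >= index_ranges[, 2])) stop("empty cycle range")
  if (any(index_ranges[, 1] < 1) || any(index_ranges[, 2] - 1 > ncol(eeg))) {
    stop("cycle range outside the EEG record")
  }
  ord <- order(index_ranges[, 1])
  if (any(index_ranges[ord, 2][-nrow(index_ranges)] >
            index_ranges[ord, 1][-1])) {
    stop("overlapping cycle ranges")
  }
  lapply(seq_len(nrow(index_ranges)), function(i) {
    eeg[, index_ranges[i, 1]:(index_ranges[i, 2] - 1L), drop = FALSE]
  })
}

#' Normalize one gait-cycle segment
#'
#' Per electrode: divide by the electrode's maximum absolute amplitude
#' within the cycle (the local peak), then resample to `n_points` evenly
#' spaced phase points spanning `[0%, 100%)` of the cycle (the next
#' contact is excluded so adjacent cycles never double-count the shared
#' boundary). Normalization precedes resampling.
#'
#' @param segment channels x L matrix, L >= 4
#' @param n_points gait-phase points (default 100)
#' @param peak `"per_electrode"` (default) or `"global"`: normalize by each
#'   electrode's own cycle peak, or by the single largest peak across all
#'   electrodes of the cycle
#' @param amplitude_normalize divide by the local peak (default); `FALSE`
#'   keeps microvolts and only time-normalizes
#' @return channels x `n_points` matrix; per-row max |value| <= 1 when
#'   amplitude-normalized
#' @export
normalize_cycle <- function(segment, n_points = 100,
                            peak = c("per_electrode", "global"),
                            amplitude_normalize = TRUE) {
  peak <- match.arg(peak)
  stopifnot(is.matrix(segment))
  L <- ncol(segment)
  if (L < 4) stop("cycle too short to resample (", L, " samples)")
  peaks <- apply(abs(segment), 1, max)
  if (any(peaks == 0)) {
    flat <- rownames(segment)[peaks == 0]
    if (is.null(flat)) flat <- which(peaks == 0)
    stop("flat (all-zero) electrode trace in cycle: ",
         paste(flat, collapse = ", "))
  }
  if (peak == "global") peaks <- rep(max(peaks), length(peaks))
  norm <- if (amplitude_normalize) segment / peaks else segment
  # sample j of the segment sits at phase (j-1)/L; target point k at
  # phase k/n_points (k = 0..n_points-1). Both grids are half-open so a
  # length-n_points segment maps onto itself exactly.
  src_pos <- (seq_len(L) - 1) / L
  target <- (seq_len(n_points) - 1L) / n_points
  out <- t(apply(norm, 1, function(r)
    stats::approx(src_pos, r, xout = target, rule = 2)$y))
  dimnames(out) <- list(rownames(segment), NULL)
  out
}

#' Ensemble-average normalized cycles into a subject cycle matrix
#'
#' Elementwise arithmetic mean of the subject's normalized 30 x 100
#' traces.
#'
#' @param traces list of equal-dimension matrices from [normalize_cycle()]
#' @param subject_id,group,condition bookkeeping carried on the result
#' @return object of class `cycle_matrix`: the averaged matrix in
#'   `values`, plus `n_cycles_averaged` and the bookkeeping fields
#' @export
ensemble_average_subject <- function(traces, subject_id = NA_character_,
                                     group = NA_character_,
                                     condition = NA_character_) {
  if (length(traces) < 1) stop("need at least one cycle trace")
  dims <- dim(traces[[1]])
  if (!all(vapply(traces, function(m) identical(dim(m), dims), TRUE))) {
    stop("cycle traces have mismatched dimensions")
  }
  values <- Reduce(`+`, traces) / length(traces)
  structure(list(values = values, n_cycles_averaged = length(traces),
                 subject_id = subject_id, group = group,
                 condition = condition),
            class = "cycle_matrix")
}

#' @export
print.cycle_matrix <- function(x, ...) {
  cat(sprintf("cycle_matrix %s [%s/%s]: %d x %d, %d cycles averaged\n",
              x$subject_id, x$group, x$condition, nrow(x$values),
              ncol(x$values), x$n_cycles_averaged))
  invisible(x)
}

#' Ensemble statistics across subjects of one design cell
#'
#' Elementwise mean and sample SD (n-1) across the subjects' cycle
#' matrices of one group x condition cell.
#'
#' @param matrices list of `cycle_matrix` objects, all from `cell`
#' @param cell the design cell (`"TsSC"`, `"TSC"`, `"OsSC"`, `"OSC"`)
#' @return object of class `group_map` with `mean`, `sd`, `cell`,
#'   `n_subjects`
#' @export
ensemble_average_group <- function(matrices, cell) {
  if (length(matrices) < 2) stop("need at least 2 subjects per cell")
  cells <- vapply(matrices, function(m) paste0(m$group, m$condition), "")
  if (!all(is.na(cells) | cells == "NANA" | cells == cell)) {
    stop("matrices from mixed cells passed to ensemble_average_group")
  }
  vals <- lapply(matrices, `[[`, "values")
  dims <- dim(vals[[1]])
  stopifnot(all(vapply(vals, function(m) identical(dim(m), dims), TRUE)))
  n <- length(vals)
  mu <- Reduce(`+`, vals) / n
  ss <- Reduce(`+`, lapply(vals, function(v) (v - mu)^2))
  structure(list(mean = mu, sd = sqrt(ss / (n - 1)), cell = cell,
                 n_subjects = n),
            class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  cat(sprintf("group_map %s: %d x %d, n = %d subjects\n", x$cell,
              nrow(x$mean), ncol(x$mean), x$n_subjects))
  invisible(x)
}

#' Build a subject's cycle matrix from a cleaned recording
#'
#' Full epoching chain for one recording: gait events -> EEG index ranges
#' -> per-cycle extraction -> per-cycle normalization -> ensemble average.
#' Only the 30 active montage electrodes enter the matrix.
#'
#' @param eeg cleaned, band-limited EEG (recorded channels x samples) with
#'   row names, or a `raw_recording`-shaped channel set
#' @param events a `gait_events` object (times on the shared clock)
#' @param eeg_rate EEG sampling rate, Hz
#' @param montage a `montage_info`
#' @param subject_id,group,condition bookkeeping
#' @return a `cycle_matrix` (30 x 100)
#' @export
subject_cycle_matrix <- function(eeg, events, eeg_rate,
                                 montage = montage_info(),
                                 subject_id = NA_character_,
                                 group = NA_character_,
                                 condition = NA_character_,
                                 amplitude_normalize = TRUE) {
  if (!is.null(rownames(eeg))) {
    idx <- match(montage$active_labels, rownames(eeg))
    if (anyNA(idx)) stop("EEG rows missing active electrodes: ",
                         paste(montage$active_labels[is.na(idx)], collapse = ", "))
    eeg <- eeg[idx, , drop = FALSE]
  } else if (nrow(eeg) != length(montage$active_labels)) {
    stop("unnamed EEG must already have exactly the 30 active rows")
  }
  ranges <- events_to_eeg_indices(events, eeg_rate, n_samples = ncol(eeg))
  segs <- extract_cycles(eeg, ranges)
  traces <- lapply(segs, normalize_cycle,
                   amplitude_normalize = amplitude_normalize)
  ensemble_average_subject(traces, subject_id = subject_id, group = group,
                           condition = condition)
}
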
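#' Construct a synchronized EEG + IMU walking recording
#'
#' Container for one subject-condition recording: multichannel EEG in
#' microvolts, the right-thigh flexion angle from the IMU in degrees, their
#' sampling rates, and sync markers placing both streams on a shared clock
#' (marker time 0 = sample 1 of both streams).
#'
#' @param eeg numeric matrix, channels x samples, microvolts
#' @param imu_angle numeric vector, thigh angle in degrees
#' @param eeg_rate EEG sampling rate, Hz (512 for conformant data)
#' @param imu_rate IMU sampling rate, Hz (200 for conformant data)
#' @param channel_labels labels for the EEG rows (default: recorded montage)
#' @param markers data.frame with columns `time_s`, `label`
#' @param subject_id,group,condition cohort bookkeeping; `group` in O/T,
#'   `condition` in sSC/SC
#' @param ground_truth optional list of generator-known quantities
#'   (contact times, embedded template, sources) for synthetic recordings
#' @return object of class `raw_recording`
#' @export
raw_recording <- function(eeg, imu_angle, eeg_rate = 512, imu_rate = 200,
                          channel_labels = recorded_labels(),
                          markers = data.frame(time_s = 0, label = "sync"),
                          subject_id = "S01", group = c("O", "T"),
                          condition = c("sSC", "SC"), ground_truth = NULL) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  stopifnot(is.matrix(eeg), nrow(eeg) == length(channel_labels),
            is.numeric(imu_angle), eeg_rate > 0, imu_rate > 0)
  structure(
    list(eeg = eeg, imu_angle = as.numeric(imu_angle),
         eeg_rate = eeg_rate, imu_rate = imu_rate,
         channel_labels = channel_labels, markers = markers,
         subject_id = subject_id, group = group, condition = condition,
         ground_truth = ground_truth),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording %s [%s/%s]: %d ch x %d EEG samples @%g Hz, %d IMU samples @%g Hz (%.1f s)\n",
              x$subject_id, x$group, x$condition, nrow(x$eeg), ncol(x$eeg),
              x$eeg_rate, length(x$imu_angle), x$imu_rate,
              ncol(x$eeg) / x$eeg_rate))
  invisible(x)
}

#' Write a recording to disk (EDF + CSV + JSON manifest)
#'
#' EEG goes to `<stem>_eeg.edf`, the IMU angle to `<stem>_imu.csv`
#' (columns `time_s`, `thigh_angle_deg`) and the metadata (rates, markers,
#' subject/group/condition) to `<stem>_manifest.json`.
#'
#' @param rec a `raw_recording`
#' @param stem path stem (directory + basename without extension)
#' @return named character vector of the three paths, invisibly
#' @export
write_recording <- function(rec, stem) {
  paths <- c(eeg = paste0(stem, "_eeg.edf"),
             imu = paste0(stem, "_imu.csv"),
             manifest = paste0(stem, "_manifest.json"))
  write_edf(rec$eeg, rec$eeg_rate, rec$channel_labels, paths[["eeg"]])
  imu <- data.frame(time_s = (seq_along(rec$imu_angle) - 1) / rec$imu_rate,
                    thigh_angle_deg = rec$imu_angle)
  utils::write.csv(imu, paths[["imu"]], row.names = FALSE)
  manifest <- list(subject_id = rec$subject_id, group = rec$group,
                   condition = rec$condition, eeg_rate = rec$eeg_rate,
                   imu_rate = rec$imu_rate, markers = rec$markers)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a recording written by [write_recording()]
#'
#' Channel labels in the EDF are matched onto the montage case- and
#' underscore-insensitively, and channels are reordered to montage order.
#' A missing active electrode is an error; missing mastoids are tolerated.
#'
#' @param stem the path stem used when writing
#' @param montage a `montage_info`
#' @return a `raw_recording`
#' @export
read_recording <- function(stem, montage = montage_info()) {
  edf <- read_edf(paste0(stem, "_eeg.edf"))
  imu <- utils::read.csv(paste0(stem, "_imu.csv"))
  man <- jsonlite::read_json(paste0(stem, "_manifest.json"), simplifyVector = TRUE)

  if (!all(c("time_s", "thigh_angle_deg") %in% names(imu))) {
    stop("IMU CSV must have columns time_s, thigh_angle_deg")
  }
  if (any(diff(imu$time_s) <= 0)) stop("non-monotone time in IMU CSV")

  idx <- match_montage(edf$labels, montage)
  present <- !is.na(idx)
  eeg <- matrix(NA_real_, nrow = length(idx), ncol = ncol(edf$data))
  eeg[present, ] <- edf$data[idx[present], , drop = FALSE]
  if (any(!present)) eeg <- eeg[present, , drop = FALSE]

  if (abs(edf$rate - man$eeg_rate) > 1e-6) {
    stop("EEG sampling rate mismatch between EDF and manifest")
  }
  imu_rate <- man$imu_rate
  dt <- diff(imu$time_s)
  if (length(dt) > 0 && abs(1 / stats::median(dt) - imu_rate) > 0.5) {
    stop("IMU sampling rate mismatch between CSV and manifest")
  }

  raw_recording(eeg, imu$thigh_angle_deg, eeg_rate = edf$rate,
                imu_rate = imu_rate,
                channel_labels = names(idx)[present],
                markers = as.data.frame(man$markers),
                subject_id = man$subject_id, group = man$group,
                condition = man$condition)
}
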
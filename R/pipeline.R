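# End-to-end orchestration: simulate (or load) -> prefilter -> ICA ->
# postfilter -> segment -> epoch -> group maps -> SnPM, with a fixed seed
# reproducing every stage bit-identically.

#' Pipeline configuration
#'
#' Collects every tunable of the chain in one serializable list. Defaults
#' mirror the slow-walking 3-min protocol; simulations in tests typically
#' shorten `duration`.
#'
#' @param n_per_group subjects per group
#' @param effect an [effect_spec()]
#' @param seed master seed (drives cohort layout, ICA init, permutations)
#' @param duration recording length, seconds
#' @param band analysis band name (delta is the results band)
#' @param notch a [notch_spec()] or `NULL`
#' @param ica list: `n_components`, `max_iter`, `tol`, `remove`
#'   (`"non_brain"` or `"all"`)
#' @param segmentation list: `min_period`, `prominence`, `policy`
#' @param epoching list: `n_points`, `amplitude_normalize`
#' @param snpm list: `n_perm`, `alpha`, `effects`, `electrodes` (labels to
#'   test; `NULL` = all 30 active)
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(n_per_group = 12, effect = null_effect(),
                            seed = 1L, duration = 180, band = "delta",
                            notch = notch_spec(),
                            ica = list(n_components = 5, max_iter = 1000,
                                       tol = 1e-4, remove = "non_brain"),
                            segmentation = list(min_period = 0.5,
                                                prominence = 5,
                                                policy = "duration"),
                            epoching = list(n_points = 100,
                                            amplitude_normalize = TRUE),
                            snpm = list(n_perm = 1000, alpha = 0.05,
                                        effects = "interaction",
                                        electrodes = NULL)) {
  structure(list(n_per_group = n_per_group, effect = effect,
                 seed = as.integer(seed), duration = duration, band = band,
                 notch = notch, ica = ica, segmentation = segmentation,
                 epoching = epoching, snpm = snpm),
            class = "pipeline_config")
}

#' Process one recording into a subject cycle matrix
#'
#' The per-recording chain: band-pass + notch prefiltering, fastICA,
#' rule-based artifact removal, band low-pass, IMU gait segmentation,
#' cycle extraction/normalization and ensemble averaging.
#'
#' @param rec a [raw_recording()]
#' @param config a [pipeline_config()]
#' @return list: `matrix` (a `cycle_matrix`), `events` (`gait_events`),
#'   `ic_labels` (classification table), `stride_count`
#' @export
process_recording <- function(rec, config = pipeline_config()) {
  band <- band_definition(config$band)
  pre <- prefilter(rec$eeg, band, config$notch, rec$eeg_rate)
  dec <- fit_fastica(pre, n_components = config$ica$n_components,
                     seed = config$seed, max_iter = config$ica$max_iter,
                     tol = config$ica$tol)
  cl <- clean_artifacts(pre, dec, rate = rec$eeg_rate,
                        remove = config$ica$remove)
  post <- postfilter(cl$cleaned, band, rec$eeg_rate)
  events <- segment_gait(rec$imu_angle, rec$imu_rate,
                         min_period = config$segmentation$min_period,
                         prominence = config$segmentation$prominence,
                         policy = config$segmentation$policy)
  cm <- subject_cycle_matrix(post, events, rec$eeg_rate,
                             subject_id = rec$subject_id, group = rec$group,
                             condition = rec$condition,
                             amplitude_normalize =
                               config$epoching$amplitude_normalize)
  # strides initiated in the walk = initial contacts (how stride tables
  # count); events$stride_count is the stricter analyzable-cycle count
  list(matrix = cm, events = events, ic_labels = cl$labels,
       stride_count = events$n_contacts,
       n_cycles = events$stride_count)
}

# stack per-subject cycle matrices into per-electrode design arrays
matrices_to_designs <- function(matrices_by_subject, montage = montage_info()) {
  subjects <- names(matrices_by_subject)
  n_points <- ncol(matrices_by_subject[[1]]$sSC$values)
  labels <- montage$active_labels
  out <- stats::setNames(lapply(labels, function(el) {
    arr <- array(0, dim = c(length(subjects), 2, n_points),
                 dimnames = list(subjects, c("sSC", "SC"), NULL))
    r <- match(el, labels)
    for (s in seq_along(subjects)) {
      arr[s, 1, ] <- matrices_by_subject[[s]]$sSC$values[r, ]
      arr[s, 2, ] <- matrices_by_subject[[s]]$SC$values[r, ]
    }
    arr
  }), labels)
  out
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates the cohort design, processes every recording subject-by-
#' subject (recordings are materialized lazily, so memory stays flat),
#' assembles the stride table, the four group-by-condition maps and the
#' per-electrode SnPM results.
#'
#' @param config a [pipeline_config()]
#' @param verbose print stage progress
#' @return object of class `run_report`: `stride_table`, `matrices`
#'   (per-subject list with `$sSC`/`$SC` cycle matrices), `group_maps`
#'   (4 cells), `snpm` (list of `snpm_result` + summary attribute),
#'   `normality`, `config`
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  cohort <- generate_cohort(n_per_group = config$n_per_group,
                            effect = config$effect, seed = config$seed,
                            duration = config$duration)
  man <- cohort$manifest
  subjects <- unique(man$subject_id)
  matrices <- stats::setNames(vector("list", length(subjects)), subjects)
  stride_rows <- list()
  for (s in subjects) {
    per_cond <- list()
    for (cond in c("sSC", "SC")) {
      i <- which(man$subject_id == s & man$condition == cond)
      rec <- materialize_recording(cohort, i)
      pr <- tryCatch(process_recording(rec, config), error = function(e) {
        stop("pipeline stage failed for subject ", s, " [", cond, "]: ",
             conditionMessage(e))
      })
      per_cond[[cond]] <- pr$matrix
      stride_rows[[paste(s, cond)]] <- data.frame(
        subject_id = s, group = man$group[i], condition = cond,
        strides = pr$stride_count)
      if (verbose) message(sprintf("%s %s: %d strides", s, cond,
                                   pr$stride_count))
    }
    matrices[[s]] <- per_cond
  }
  stride_long <- do.call(rbind, stride_rows)
  stride_table <- data.frame(
    subject_id = subjects,
    group = man$group[match(subjects, man$subject_id)],
    steps_sSC = stride_long$strides[stride_long$condition == "sSC"][
      match(subjects, stride_long$subject_id[stride_long$condition == "sSC"])],
    steps_SC = stride_long$strides[stride_long$condition == "SC"][
      match(subjects, stride_long$subject_id[stride_long$condition == "SC"])])
  class(stride_table) <- c("step_table", "data.frame")

  cells <- c("TsSC", "TSC", "OsSC", "OSC")
  group_maps <- stats::setNames(lapply(cells, function(cell) {
    g <- substr(cell, 1, 1); cond <- sub("^[OT]", "", cell)
    sel <- subjects[man$group[match(subjects, man$subject_id)] == g]
    ensemble_average_group(lapply(sel, function(s) matrices[[s]][[cond]]),
                           cell)
  }), cells)

  designs <- matrices_to_designs(matrices)
  if (!is.null(config$snpm$electrodes)) {
    designs <- designs[config$snpm$electrodes]
  }
  group_vec <- man$group[match(subjects, man$subject_id)]
  normality <- normality_check(
    snpm_design(designs[[1]], group_vec, names(designs)[1]))
  snpm_res <- run_snpm_all_electrodes(designs, group_vec,
                                      effects = config$snpm$effects,
                                      n_perm = config$snpm$n_perm,
                                      alpha = config$snpm$alpha,
                                      seed = config$seed)
  structure(list(stride_table = stride_table, matrices = matrices,
                 group_maps = group_maps, snpm = snpm_res,
                 normality = normality, config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d subjects, band = %s\n",
              nrow(x$stride_table), x$config$band))
  summ <- attr(x$snpm, "summary")
  if (nrow(summ) == 0) cat("  no significant modulation\n")
  else print(summ)
  invisible(x)
}

# conventional percent boundaries for the named gait phases (Perry's
# subdivisions); a cluster is labeled by majority overlap
gait_phase_table <- function() {
  data.frame(phase = c("loading response", "mid stance", "terminal stance",
                       "pre-swing", "swing"),
             start = c(0, 10, 30, 50, 60),
             end = c(10, 30, 50, 60, 100))
}

#' Name the gait phase of a cluster window
#'
#' @param start_pct,end_pct cluster extent in percent of the gait cycle
#' @return the phase name whose range overlaps the window most
#' @export
gait_phase_name <- function(start_pct, end_pct) {
  tab <- gait_phase_table()
  overlap <- pmax(0, pmin(end_pct, tab$end) - pmax(start_pct, tab$start))
  if (all(overlap == 0)) {       # degenerate (point) window: locate it
    inside <- start_pct >= tab$start & start_pct <= tab$end
    return(tab$phase[which(inside)[1]])
  }
  tab$phase[which.max(overlap)]
}

#' Summarize a pipeline run
#'
#' Human-readable text plus a JSON-ready list of the significant
#' electrode/effect clusters, each labeled with its gait phase.
#'
#' @param run a `run_report` from [run_pipeline()]
#' @return list with `text` (character vector of lines) and `table`
#'   (data.frame incl. `phase` labels), invisibly printable
#' @export
report_summary <- function(run) {
  summ <- attr(run$snpm, "summary")
  if (is.null(summ) || nrow(summ) == 0) {
    return(list(text = "no significant modulation",
                table = data.frame()))
  }
  summ$phase <- mapply(gait_phase_name, summ$start_pct, summ$end_pct)
  lines <- sprintf(
    "%s: %s effect, %.1f%%-%.1f%% of gait cycle (%s), Fmax = %.2f, p = %.4f",
    summ$electrode, summ$effect, summ$start_pct, summ$end_pct, summ$phase,
    summ$F_max, summ$p_cluster)
  list(text = lines, table = summ)
}
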
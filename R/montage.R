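#' Standard 32-electrode walking-EEG montage
#'
#' The acquisition montage used throughout the package: 30 active scalp
#' electrodes of the 10-20 system plus the two mastoids. The online
#' reference (CPz) and ground (AFz) carry no signal of their own and are
#' excluded from every analysis matrix; the mastoids are recorded but not
#' analyzed, so electrode-by-phase matrices always have 30 rows.
#'
#' @return An object of class `montage_info` with elements
#'   `active_labels` (character, length 30, fixed analysis row order),
#'   `mastoids` (`M1`, `M2`), `reference` (`CPz`) and `ground` (`AFz`).
#' @examples
#' m <- montage_info()
#' length(m$active_labels)  # 30
#' @export
montage_info <- function() {
  active <- c("Fp1", "Fp2", "Fpz", "F3", "F4", "F7", "F8", "Fz",
              "FC1", "FC2", "FC5", "FC6", "C3", "C4", "Cz", "T7", "T8",
              "CP1", "CP2", "CP5", "CP6", "P3", "P4", "P7", "P8", "Pz",
              "POz", "O1", "O2", "Oz")
  stopifnot(length(active) == 30L, !anyDuplicated(active))
  structure(
    list(active_labels = active,
         mastoids = c("M1", "M2"),
         reference = "CPz",
         ground = "AFz"),
    class = "montage_info"
  )
}

#' @export
print.montage_info <- function(x, ...) {
  cat("10-20 walking-EEG montage: 30 active electrodes",
      sprintf("(+ mastoids %s; ref %s, gnd %s)\n",
              paste(x$mastoids, collapse = "/"), x$reference, x$ground))
  invisible(x)
}

#' All recorded channel labels (active + mastoids)
#'
#' @param montage a `montage_info` object
#' @return character vector of 32 labels in recording order
#' @export
recorded_labels <- function(montage = montage_info()) {
  c(montage$active_labels, montage$mastoids)
}

# Canonicalize a channel label for matching: case- and underscore-insensitive.
normalize_label <- function(x) toupper(gsub("[ _]", "", x))

#' Match channel labels against the montage
#'
#' Maps arbitrary-case, possibly underscored labels (e.g. `"FC_1"`, `"fz"`)
#' onto canonical montage labels.
#'
#' @param labels character vector of channel labels as found in a file
#' @param montage a `montage_info`
#' @return integer vector: for each recorded montage channel, its index in
#'   `labels`. Errors if any active electrode is missing; missing mastoids
#'   are tolerated (index `NA`).
#' @export
match_montage <- function(labels, montage = montage_info()) {
  want <- recorded_labels(montage)
  idx <- match(normalize_label(want), normalize_label(labels))
  missing_active <- want[seq_len(30)][is.na(idx[seq_len(30)])]
  if (length(missing_active) > 0) {
    stop("active electrode(s) missing from recording: ",
         paste(missing_active, collapse = ", "))
  }
  names(idx) <- want
  idx
}

# half-away-from-zero rounding to `digits` decimals (R's round() is
# round-half-even; summary tables use the conventional half-up rule)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a per-subject stride-count table
#'
#' Reads a CSV with columns `subject_id`, `group` (O/T), `steps_sSC`,
#' `steps_SC`: the number of strides each subject completed in the 3-min
#' walk under each speed-control condition. The packaged fixture
#' (`system.file("extdata", "stride_counts.csv", package = "gaitwave")`)
#' holds the 24-subject cohort table the synthetic gait models are
#' calibrated against.
#'
#' @param path path to the CSV file
#' @return a `data.frame` of class `step_table`
#' @export
read_step_table <- function(path) {
  # group "T" must never be type-converted to logical TRUE
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(group = "character"))
  need <- c("subject_id", "group", "steps_sSC", "steps_SC")
  if (nrow(tab) == 0L) stop("empty stride-count table: ", path)
  if (!all(need %in% names(tab))) {
    stop("stride-count table must have columns ", paste(need, collapse = ", "))
  }
  if (!all(tab$group %in% c("O", "T"))) stop("group must be 'O' or 'T'")
  for (col in c("steps_sSC", "steps_SC")) {
    v <- tab[[col]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      stop("step counts in ", col, " must be non-negative integers")
    }
  }
  class(tab) <- c("step_table", "data.frame")
  tab
}

#' Summarize stride counts per group and condition
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of
#' stride counts for each group x condition cell, rounded
#' half-away-from-zero to one decimal, matching how cohort stride tables
#' are conventionally reported.
#'
#' @param table a `step_table` from [read_step_table()]
#' @return data.frame with columns `group`, `condition`, `mean`, `sd`, `n`
#' @export
summarize_steps <- function(table) {
  n_per_group <- vapply(c("O", "T"), function(g) sum(table$group == g), 0L)
  if (any(n_per_group < 2)) stop("need at least 2 subjects per group")
  long <- rbind(
    data.frame(group = table$group, condition = "sSC", steps = table$steps_sSC),
    data.frame(group = table$group, condition = "SC", steps = table$steps_SC)
  )
  out <- do.call(rbind, lapply(split(long, long[c("group", "condition")]), function(d) {
    data.frame(group = d$group[1], condition = d$condition[1],
               mean = round_half_up(mean(d$steps), 1),
               sd = round_half_up(stats::sd(d$steps), 1),
               n = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$group, out$condition, decreasing = c(FALSE, TRUE), method = "radix"), ,
      drop = FALSE]
}
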
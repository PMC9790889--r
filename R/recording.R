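#' Standard 22-channel motor-imagery montage
#'
#' Channel labels of the 22-electrode montage used by four-class
#' cued motor-imagery recordings (fronto-central to parietal coverage),
#' in their conventional order.
#'
#' @return Character vector of 22 channel names.
#' @export
mi22_channels <- function() {
  c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP3", "CP1", "CPz", "CP2", "CP4", "P1", "Pz", "P2", "POz")
}

#' Default brain-region channel grouping
#'
#' Disjoint frontal / central / parietal groups over the standard
#' 22-channel montage, used for region-averaged accuracy reporting.
#'
#' @return Named list of character vectors.
#' @export
default_region_map <- function() {
  list(
    frontal  = c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4"),
    central  = c("C5", "C3", "C1", "Cz", "C2", "C4", "C6"),
    parietal = c("CP3", "CP1", "CPz", "CP2", "CP4", "P1", "Pz", "P2", "POz")
  )
}

#' Epoched multi-channel EEG recording
#'
#' The universal input container of the pipeline: a labelled trial tensor
#' with sampling metadata. Labels are integer class ids in `0..K-1`
#' (class names carry the human-readable labels).
#'
#' @param signals Numeric array `[n_trials, n_channels, n_samples]`.
#' @param labels Integer vector of per-trial class ids in `0..K-1`.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one per channel.
#' @param class_names Character vector, one per class.
#' @param trial_onset Seconds of each epoch's `t = 0` relative to cue onset.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, labels, fs,
                          channel_names = NULL,
                          class_names = NULL,
                          trial_onset = 0) {
  check_that(is.array(signals) && length(dim(signals)) == 3L,
             "signals must be a 3-d array [trials x channels x samples]")
  labels <- as.integer(labels)
  if (is.null(class_names)) {
    class_names <- paste0("class", sort(unique(labels)))
  }
  if (is.null(channel_names)) {
    channel_names <- if (dim(signals)[2] == 22L) mi22_channels() else
      paste0("ch", seq_len(dim(signals)[2]))
  }
  rec <- structure(
    list(signals = signals, labels = labels, fs = fs,
         channel_names = channel_names, class_names = class_names,
         trial_onset = trial_onset),
    class = "eeg_recording")
  validate_recording(rec)
  rec
}

#' Validate an epoched recording
#'
#' Checks the structural invariants: finite signal values, label/channel
#' bookkeeping, and labels within `0..K-1`.
#'
#' @param rec An `eeg_recording`.
#' @return Invisibly, `rec`.
#' @export
validate_recording <- function(rec) {
  d <- dim(rec$signals)
  check_that(all(is.finite(rec$signals)),
             "signals contain NaN/Inf values", "validation_error")
  check_that(length(rec$labels) == d[1],
             sprintf("labels length %d != n_trials %d",
                     length(rec$labels), d[1]), "validation_error")
  k <- length(rec$class_names)
  check_that(all(rec$labels >= 0L & rec$labels < k),
             sprintf("labels must lie in 0..%d", k - 1L), "validation_error")
  check_that(length(rec$channel_names) == d[2],
             sprintf("channel_names length %d != n_channels %d",
                     length(rec$channel_names), d[2]), "validation_error")
  check_that(is.numeric(rec$fs) && rec$fs > 0, "fs must be positive",
             "validation_error")
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("<eeg_recording> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  classes:", paste(x$class_names, collapse = ", "), "\n")
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L))
  cat("  trials/class:", paste(tab, collapse = ", "), "\n")
  invisible(x)
}

#' Subset the channels of a recording
#'
#' @param rec An `eeg_recording`.
#' @param channels Character channel names or integer indices to keep.
#' @return An `eeg_recording` with the selected channels.
#' @export
select_channels <- function(rec, channels) {
  if (is.character(channels)) {
    idx <- match(channels, rec$channel_names)
    if (anyNA(idx)) {
      clfc_error(sprintf("unknown channel(s): %s",
                         paste(channels[is.na(idx)], collapse = ", ")),
                 "lookup_error")
    }
  } else {
    idx <- as.integer(channels)
    check_that(all(idx >= 1L & idx <= dim(rec$signals)[2]),
               "channel index out of range", "lookup_error")
  }
  eeg_recording(rec$signals[, idx, , drop = FALSE], rec$labels, rec$fs,
                rec$channel_names[idx], rec$class_names, rec$trial_onset)
}
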
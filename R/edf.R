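# Minimal EDF/EDF+ support: enough of the European Data Format to write
# small continuous test recordings with embedded annotations and to import
# real cue-based sessions as labelled epochs. 16-bit samples, fixed-length
# data records, annotations as EDF+ time-stamped annotation lists (TALs).
# GDF is not parsed; requests for it fail with a clear error.

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

#' Write a minimal EDF+ file
#'
#' Intended for building small test recordings: continuous signals, one
#' data record per second, 16-bit samples, and an optional EDF Annotations
#' channel carrying event onsets.
#'
#' @param signals `[n_channels x n_samples]` matrix of physical values.
#' @param fs Sampling rate in Hz (samples per data record).
#' @param path Output path.
#' @param channel_names Channel labels.
#' @param events Optional `data.frame` with columns `onset` (seconds) and
#'   `label` (character).
#' @return Invisibly, `path`.
#' @export
write_edf <- function(signals, fs, path, channel_names = NULL,
                      events = NULL) {
  check_that(is.matrix(signals) && all(is.finite(signals)),
             "signals must be a finite [channels x samples] matrix")
  nch <- nrow(signals); nsamp <- ncol(signals)
  check_that(nsamp %% fs == 0, "signal length must be whole seconds")
  n_rec <- nsamp %/% fs
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  has_annot <- !is.null(events)
  ns_total <- nch + as.integer(has_annot)
  annot_len <- 60L                      # 2-byte samples per record

  phys_min <- apply(signals, 1, min); phys_max <- apply(signals, 1, max)
  span <- pmax(phys_max - phys_min, 1e-6)
  phys_min <- phys_min - 0.01 * span; phys_max <- phys_max + 0.01 * span
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, width, eos = NULL)
  wr("0", 8)                            # version
  wr("X X X X", 80)                     # patient id (anonymous)
  wr("Startdate 01-JAN-2000 X X X", 80) # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)  # date, time
  wr(256 * (1 + ns_total), 8)           # header bytes
  wr(if (has_annot) "EDF+C" else "", 44)
  wr(n_rec, 8)
  wr("1", 8)                            # record duration (s)
  wr(ns_total, 4)
  labels <- c(channel_names, if (has_annot) "EDF Annotations")
  for (lb in labels) wr(lb, 16)
  for (i in seq_len(ns_total)) wr("", 80)   # transducer
  wr_each <- function(vals, width) for (v in vals) wr(v, width)
  wr_each(c(rep("uV", nch), if (has_annot) ""), 8)
  wr_each(c(sprintf("%.6g", phys_min), if (has_annot) "-1"), 8)
  wr_each(c(sprintf("%.6g", phys_max), if (has_annot) "1"), 8)
  wr_each(c(rep(dig_min, nch), if (has_annot) dig_min), 8)
  wr_each(c(rep(dig_max, nch), if (has_annot) dig_max), 8)
  for (i in seq_len(ns_total)) wr("", 80)   # prefiltering
  wr_each(c(rep(fs, nch), if (has_annot) annot_len), 8)
  for (i in seq_len(ns_total)) wr("", 32)   # reserved

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- round((signals[ch, idx] - phys_min[ch]) * scale[ch] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
    if (has_annot) {
      # record time-keeping TAL, then one nul-terminated TAL per event
      raw_tal <- c(charToRaw(sprintf("+%g\x14\x14", r - 1L)), as.raw(0))
      in_rec <- events[events$onset >= r - 1L & events$onset < r, ,
                       drop = FALSE]
      for (e in seq_len(nrow(in_rec))) {
        raw_tal <- c(raw_tal,
                     charToRaw(sprintf("+%.10g\x14%s\x14", in_rec$onset[e],
                                       in_rec$label[e])),
                     as.raw(0))
      }
      buf <- raw(2L * annot_len)
      check_that(length(raw_tal) <= length(buf),
                 "too many events in one record", "io_error")
      buf[seq_along(raw_tal)] <- raw_tal
      writeBin(buf, con)
    }
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' Parses the header, converts samples to physical units, and extracts
#' events from an `EDF Annotations` channel when present. The sampling
#' rate is read from the file and never silently resampled.
#'
#' @param path EDF file path.
#' @return List with `signals` `[n_channels x n_samples]`, `fs`,
#'   `channel_names`, and `events` (`data.frame` of `onset`, `label`;
#'   empty when no annotation channel exists).
#' @export
read_edf <- function(path) {
  check_that(file.exists(path), sprintf("no such file: %s", path),
             "io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  check_that(version == "0", "not an EDF file (bad version field)",
             "import_error")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)                                 # reserved / EDF+ marker
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)           # units
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  is_annot <- labels == "EDF Annotations"
  sig_idx <- which(!is_annot)
  fs <- spr[sig_idx[1]] / rec_dur
  sig <- matrix(0, length(sig_idx), n_rec * spr[sig_idx[1]])
  events <- list()
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_annot[i]) {
        buf <- readBin(con, "raw", 2L * spr[i])
        # TALs are nul-terminated; an annotation TAL is onset \x14 text \x14
        zero <- which(buf == as.raw(0))
        starts <- c(1L, zero + 1L)
        ends <- c(zero - 1L, length(buf))
        for (s in seq_along(starts)) {
          if (starts[s] > ends[s]) next
          txt <- rawToChar(buf[starts[s]:ends[s]])
          parts <- strsplit(txt, "\x14", fixed = TRUE)[[1]]
          if (length(parts) >= 2 && nzchar(parts[2])) {
            events[[length(events) + 1L]] <-
              data.frame(onset = as.numeric(parts[1]),
                         label = parts[2], stringsAsFactors = FALSE)
          }
        }
      } else {
        dig <- readBin(con, "integer", spr[i], size = 2, endian = "little")
        j <- match(i, sig_idx)
        phys <- (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) /
          (dig_max[i] - dig_min[i]) + phys_min[i]
        sig[j, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
      }
    }
  }
  ev <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(onset = numeric(0), label = character(0))
  list(signals = sig, fs = fs,
       channel_names = trimws(labels[sig_idx]), events = ev)
}

#' Import a standard EEG recording as labelled epochs
#'
#' Cuts epochs at `[onset + window[1], onset + window[2])` seconds around
#' each event (sample index `floor(t * fs)`), mapping event labels to
#' 0-based class ids. The sampling rate comes from the file.
#'
#' @param path Recording path.
#' @param format `"edf"` (supported) or `"gdf"` (rejected: no parser is
#'   bundled).
#' @param epoch_window `c(start, end)` seconds relative to each event.
#' @param channels Optional channel-name subset.
#' @param event_map Optional named integer vector mapping event labels to
#'   class ids; by default labels are sorted and numbered from 0.
#' @return An [eeg_recording()].
#' @export
import_recording <- function(path, format = c("edf", "gdf"),
                             epoch_window = c(0, 4), channels = NULL,
                             event_map = NULL) {
  format <- match.arg(format)
  if (format == "gdf") {
    clfc_error("GDF import is not supported: no GDF parser is bundled; convert to EDF",
               "import_error")
  }
  edf <- read_edf(path)
  if (nrow(edf$events) == 0) {
    clfc_error("recording has no event annotations; cannot epoch",
               "import_error")
  }
  check_that(length(epoch_window) == 2L && epoch_window[2] > epoch_window[1],
             "epoch_window must be c(start, end) with end > start")
  if (!is.null(channels)) {
    idx <- match(channels, edf$channel_names)
    if (anyNA(idx)) {
      clfc_error(sprintf("unknown channel(s): %s",
                         paste(channels[is.na(idx)], collapse = ", ")),
                 "lookup_error")
    }
  } else {
    idx <- seq_len(nrow(edf$signals))
  }
  fs <- edf$fs
  len <- floor(epoch_window[2] * fs) - floor(epoch_window[1] * fs)
  n_total <- ncol(edf$signals)
  if (is.null(event_map)) {
    lv <- sort(unique(edf$events$label))
    event_map <- stats::setNames(seq_along(lv) - 1L, lv)
  }
  n_ev <- nrow(edf$events)
  out <- array(0, c(n_ev, length(idx), len))
  labels <- integer(n_ev)
  for (e in seq_len(n_ev)) {
    s0 <- floor((edf$events$onset[e] + epoch_window[1]) * fs)
    if (s0 < 0 || s0 + len > n_total) {
      clfc_error(sprintf(
        "epoch window [%g, %g) s around event at %g s exceeds the record",
        epoch_window[1], epoch_window[2], edf$events$onset[e]),
        "bounds_error")
    }
    out[e, , ] <- edf$signals[idx, (s0 + 1L):(s0 + len), drop = FALSE]
    labels[e] <- event_map[[edf$events$label[e]]]
  }
  eeg_recording(out, labels, fs,
                channel_names = edf$channel_names[idx],
                class_names = names(event_map)[order(unlist(event_map))],
                trial_onset = epoch_window[1])
}
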
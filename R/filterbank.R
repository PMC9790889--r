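# Band-pass filter bank and multi-scale time-step segmentation.
#
# Filters are designed with signal::butter. Zero-phase application goes
# through the frequency domain (the |H|^2 response forward-backward
# filtering realizes, on a shared padded FFT), so thousands of
# trial/channel series are filtered in one pass; single-pass application
# uses stats::filter's compiled recursion.

#' Filter bank specification
#'
#' @param bands List of `c(low, high)` pairs in Hz. Default: nine contiguous
#'   4-Hz bands, 4-8 up to 36-40 Hz.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective magnitude response is the squared order-n response).
#' @param design Filter family; only `"butterworth"` is implemented.
#' @param zero_phase Apply forward-backward (no group delay)?
#' @return An object of class `filter_bank_spec`.
#' @export
filter_bank_spec <- function(bands = default_filter_bands(),
                             filter_order = 4L,
                             design = "butterworth",
                             zero_phase = TRUE) {
  design <- match.arg(design, "butterworth")
  check_that(is.list(bands) && length(bands) >= 1L, "bands must be a list")
  for (b in bands) {
    check_that(length(b) == 2L && b[1] > 0 && b[2] > b[1],
               sprintf("invalid band (%s)", paste(b, collapse = ", ")),
               "design_error")
  }
  check_that(is_count(filter_order), "filter_order must be a positive count")
  structure(list(bands = bands, filter_order = as.integer(filter_order),
                 design = design, zero_phase = isTRUE(zero_phase)),
            class = "filter_bank_spec")
}

#' Default nine-band filter bank edges
#'
#' @return List of nine `c(low, high)` pairs: 4-8, 8-12, ..., 36-40 Hz.
#' @export
default_filter_bands <- function() {
  lapply(seq(4, 36, by = 4), function(lo) c(lo, lo + 4))
}

#' Design the band-pass filter bank
#'
#' @param spec A [filter_bank_spec()].
#' @param fs Sampling rate in Hz.
#' @return Object of class `filter_bank` holding per-band `b`/`a`
#'   coefficients and metadata.
#' @export
design_filter_bank <- function(spec, fs) {
  check_that(inherits(spec, "filter_bank_spec"), "spec must be a filter_bank_spec")
  nyq <- fs / 2
  filters <- lapply(spec$bands, function(band) {
    if (band[2] >= nyq) {
      clfc_error(sprintf("band edge %g Hz is not below Nyquist (%g Hz)",
                         band[2], nyq), "design_error")
    }
    bf <- signal::butter(spec$filter_order, band / nyq, type = "pass")
    list(b = bf$b, a = bf$a, band = band)
  })
  structure(list(filters = filters, fs = fs, spec = spec),
            class = "filter_bank")
}

# single-pass IIR on the columns of x (time down the rows), run through
# stats::filter's compiled convolution + recursion. `steady_init = TRUE`
# starts each column from the steady state of a constant input equal to its
# first sample (so filtering a constant yields that constant exactly);
# FALSE starts from rest (all-zero state).
iir_filter_mat <- function(b, a, x, steady_init = FALSE) {
  b <- b / a[1]; a <- a / a[1]
  x <- as.matrix(x)
  nt <- nrow(x); ns <- ncol(x)
  nb <- length(b); na_ <- length(a)
  x0 <- if (steady_init) x[1, ] else numeric(ns)
  # moving-average part, assuming x[t <= 0] = x0
  pre <- matrix(x0, nb - 1L, ns, byrow = TRUE)
  if (nb > 1L) {
    u <- stats::filter(rbind(pre, x), b, method = "convolution", sides = 1)
    u <- u[nb:(nb + nt - 1L), , drop = FALSE]
  } else {
    u <- b[1] * x
  }
  if (na_ == 1L) return(matrix(u, nt, ns))
  # autoregressive part, with y[t <= 0] at the matching steady state
  y0 <- x0 * sum(b) / sum(a)
  init <- matrix(y0, na_ - 1L, ns, byrow = TRUE)
  y <- stats::filter(u, -a[-1], method = "recursive", init = init)
  matrix(y, nt, ns)
}

# squared magnitude response of (b, a) at the two-sided FFT bin frequencies
# of an n-point transform -- the response realized by forward-backward
# application of the filter
h2_at_bins <- function(b, a, n) {
  z <- exp(-2i * pi * (seq_len(n) - 1L) / n)
  num <- rowSums(outer(z, seq_along(b) - 1L, "^") *
                   rep(b, each = n))
  den <- rowSums(outer(z, seq_along(a) - 1L, "^") *
                   rep(a, each = n))
  Mod(num / den)^2
}

# split a minimum two-sided pad so that the padded length is 2-3-5-smooth
# (fast mixed-radix FFT)
good_fft_pad <- function(nt, min_pad) {
  np <- stats::nextn(nt + 2L * min_pad, c(2L, 3L, 5L))
  list(left = min_pad, right = np - nt - min_pad, n = np)
}

# zero-phase filtering of matrix columns in the frequency domain: multiply
# the spectrum by |H|^2 (the exact forward-backward magnitude response,
# identically zero phase). Odd-symmetric reflective padding suppresses the
# circular wrap-around. `spectrum`, if given, is the precomputed mvfft of
# the padded input (shared across the bands of a filter bank).
zerophase_fft_mat <- function(b, a, x, pad = NULL, spectrum = NULL) {
  x <- as.matrix(x)
  nt <- nrow(x)
  if (is.null(pad)) pad <- min(nt - 1L, max(3L * (length(a) - 1L), 24L))
  pd <- good_fft_pad(nt, pad)
  if (is.null(spectrum)) {
    spectrum <- stats::mvfft(reflect_pad(x, pd$left, pd$right))
  }
  h2 <- h2_at_bins(b, a, pd$n)
  y <- Re(stats::mvfft(spectrum * h2, inverse = TRUE)) / pd$n
  y[(pd$left + 1L):(pd$left + nt), , drop = FALSE]
}

# odd-symmetric (edge-anchored) reflective padding; pads beyond nt - 1 are
# filled with the edge value
reflect_pad <- function(x, left, right = left) {
  nt <- nrow(x)
  mirror <- function(edge_row, pad, idx, extend_after) {
    if (pad <= 0L) return(NULL)
    k <- min(pad, nt - 1L)
    blk <- 2 * matrix(edge_row, k, ncol(x), byrow = TRUE) -
      x[idx(k), , drop = FALSE]
    if (pad > k) {
      ext <- matrix(blk[if (extend_after) k else 1L, ], pad - k,
                    ncol(x), byrow = TRUE)
      blk <- if (extend_after) rbind(blk, ext) else rbind(ext, blk)
    }
    blk
  }
  top <- mirror(x[1, ], left, function(k) (k + 1L):2L, extend_after = FALSE)
  bot <- mirror(x[nt, ], right, function(k) (nt - 1L):(nt - k),
                extend_after = TRUE)
  rbind(top, x, bot)
}

# zero-phase filtering of matrix columns with odd-symmetric reflective padding
filtfilt_mat <- function(b, a, x, pad = NULL) {
  x <- as.matrix(x)
  nt <- nrow(x)
  if (is.null(pad)) pad <- min(nt - 1L, max(3L * (length(a) - 1L), 24L))
  xp <- reflect_pad(x, pad)
  y <- iir_filter_mat(b, a, xp, steady_init = TRUE)
  y <- iir_filter_mat(b, a, y[nrow(y):1, , drop = FALSE], steady_init = TRUE)
  y <- y[nrow(y):1, , drop = FALSE]
  if (pad > 0L) y <- y[(pad + 1L):(pad + nt), , drop = FALSE]
  y
}

#' Apply the filter bank to an epoched recording
#'
#' Each trial/channel series is band-passed by every filter of the bank.
#' Zero-phase application introduces no group delay; reflective padding
#' suppresses edge transients.
#'
#' @param recording An [eeg_recording()] (or a 3-d array with matching `fs`).
#' @param bank A designed [design_filter_bank()] result.
#' @param pad Padding duration in seconds used around each epoch before
#'   filtering (default 0.5 s).
#' @return Array `[n_trials, n_bands, n_channels, n_samples]` with the band
#'   edges attached as attribute `bands`.
#' @export
apply_filter_bank <- function(recording, bank, pad = 0.5) {
  check_that(inherits(bank, "filter_bank"), "bank must be a designed filter_bank")
  if (inherits(recording, "eeg_recording")) {
    check_that(isTRUE(all.equal(recording$fs, bank$fs)),
               sprintf("recording fs (%g) differs from design fs (%g)",
                       recording$fs, bank$fs), "contract_error")
    x <- recording$signals
  } else {
    x <- recording
  }
  d <- dim(x)
  n_bands <- length(bank$filters)
  # series as columns: [samples x (trials*channels)]
  xm <- matrix(aperm(x, c(3, 1, 2)), nrow = d[3])
  pad_n <- min(d[3] - 1L, round(pad * bank$fs))
  out <- array(0, c(d[1], n_bands, d[2], d[3]))
  pd <- good_fft_pad(d[3], pad_n)
  spectrum <- if (bank$spec$zero_phase)
    stats::mvfft(reflect_pad(xm, pd$left, pd$right))
  for (bi in seq_len(n_bands)) {
    f <- bank$filters[[bi]]
    if (bank$spec$zero_phase) {
      ym <- zerophase_fft_mat(f$b, f$a, xm, pad = pad_n,
                              spectrum = spectrum)
    } else {
      ym <- iir_filter_mat(f$b, f$a, xm)
    }
    out[, bi, , ] <- aperm(array(ym, c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  attr(out, "bands") <- bank$spec$bands
  attr(out, "fs") <- bank$fs
  out
}

#' Multi-scale time-step specification
#'
#' The seven default analysis windows (seconds, relative to trial start):
#' 2.5-3.5, 3-4, 4-5, 5-6, 2.5-4.5, 4-6 and 2.5-6.
#'
#' @param intervals List of `c(start, end)` pairs in seconds.
#' @param reference Interpretation of interval times; `"trial_start"`
#'   (default) or `"cue_onset"`.
#' @return Object of class `time_step_spec`.
#' @export
time_step_spec <- function(intervals = default_time_steps(),
                           reference = c("trial_start", "cue_onset")) {
  reference <- match.arg(reference)
  for (iv in intervals) {
    check_that(length(iv) == 2L && iv[2] > iv[1],
               sprintf("invalid interval (%s)", paste(iv, collapse = ", ")),
               "contract_error")
  }
  structure(list(intervals = intervals, reference = reference),
            class = "time_step_spec")
}

#' Default seven analysis windows
#' @return List of seven `c(start, end)` pairs in seconds.
#' @export
default_time_steps <- function() {
  list(c(2.5, 3.5), c(3, 4), c(4, 5), c(5, 6),
       c(2.5, 4.5), c(4, 6), c(2.5, 6))
}

#' Cut band-filtered epochs into multi-scale time-step blocks
#'
#' Windows are half-open `[start, end)` with start index `round(start * fs)`
#' and length `round((end - start) * fs)` samples, so interval lengths (not
#' endpoints) drive downstream shapes.
#'
#' @param band_tensor Output of [apply_filter_bank()],
#'   `[trials, bands, channels, samples]`.
#' @param steps A [time_step_spec()].
#' @param fs Sampling rate in Hz.
#' @param t0 Epoch time of the first sample in the `steps` reference frame
#'   (seconds; default 0).
#' @return Object of class `msfb_tensor`: per-(band, step) arrays
#'   `[trials, channels, samples]` plus band/step metadata.
#' @export
segment_time_steps <- function(band_tensor, steps, fs, t0 = 0) {
  check_that(inherits(steps, "time_step_spec"), "steps must be a time_step_spec")
  d <- dim(band_tensor)
  check_that(length(d) == 4L, "band_tensor must be 4-d [trials,bands,channels,samples]")
  n_samp <- d[4]
  blocks <- vector("list", d[2])
  for (bi in seq_len(d[2])) {
    blocks[[bi]] <- vector("list", length(steps$intervals))
    for (ti in seq_along(steps$intervals)) {
      iv <- steps$intervals[[ti]]
      start <- round((iv[1] - t0) * fs)
      len <- round((iv[2] - iv[1]) * fs)
      if (start < 0 || start + len > n_samp) {
        clfc_error(sprintf(
          "interval %g-%g s is outside the epoch (%d samples at %g Hz)",
          iv[1], iv[2], n_samp, fs), "bounds_error")
      }
      blk <- band_tensor[, bi, , (start + 1L):(start + len), drop = FALSE]
      dim(blk) <- c(d[1], d[3], len)   # squeeze the singleton band axis
      blocks[[bi]][[ti]] <- blk
    }
  }
  structure(list(blocks = blocks,
                 bands = attr(band_tensor, "bands"),
                 intervals = steps$intervals,
                 n_bands = d[2], n_steps = length(steps$intervals),
                 n_trials = d[1], n_channels = d[3], fs = fs),
            class = "msfb_tensor")
}
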
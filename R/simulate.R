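# Synthetic motor-imagery session generator.
#
# Each class owns one latent band-limited oscillatory source (filtered-noise
# oscillator band-passed to the class band). On trials of class k the k-th
# source's standard deviation is scaled up, so class membership is carried by
# band-limited power in a fixed spatial pattern -- exactly the structure CSP
# is built to recover. Background noise is white or 1/f ("pink").

#' Simulation configuration
#'
#' Defaults emulate one session of a four-class cued motor-imagery
#' recording: 4 classes x 72 trials, 22 channels at 250 Hz, 4 s of
#' imagery per trial. Classes 0/1 modulate a mu-band source (8-12 Hz),
#' classes 2/3 a beta-band source (20-24 Hz).
#'
#' @param n_classes Number of classes (default 4).
#' @param trials_per_class Trials per class (default 72).
#' @param n_channels Number of channels (default 22).
#' @param fs Sampling rate in Hz (default 250).
#' @param trial_duration Seconds of motor imagery per epoch (default 4).
#' @param include_fixation Prepend fixation + cue segments so that analysis
#'   windows defined on the full trial timeline (e.g. 2.5-6 s) can be
#'   indexed (default `FALSE`: epochs cover the imagery window only).
#' @param fixation_duration Seconds of pre-cue fixation (default 2).
#' @param cue_duration Seconds of cue presentation (default 1.25).
#' @param source_bands List of per-class `c(low, high)` bands in Hz.
#' @param class_gain Multiplier on the class source's standard deviation on
#'   its own trials (default 2).
#' @param mixing_matrix `"random-orthonormal"` (default) or a numeric
#'   `[n_channels x n_classes]` matrix of full column rank.
#' @param snr_db Signal-to-noise ratio in dB (source power over noise power,
#'   per trial; default 6).
#' @param noise_model `"pink"` (default) or `"white"` background noise.
#' @param seed Integer seed; fully determines the generated session.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_classes = 4L, trials_per_class = 72L,
                              n_channels = 22L, fs = 250,
                              trial_duration = 4.0,
                              include_fixation = FALSE,
                              fixation_duration = 2.0, cue_duration = 1.25,
                              source_bands = NULL,
                              class_gain = 2.0,
                              mixing_matrix = "random-orthonormal",
                              snr_db = 6, noise_model = c("pink", "white"),
                              seed = 1L) {
  noise_model <- match.arg(noise_model)
  check_that(is_count(n_classes, 2L), "n_classes must be >= 2",
             "configuration_error")
  check_that(is_count(trials_per_class), "trials_per_class must be positive",
             "configuration_error")
  check_that(is_count(n_channels), "n_channels must be positive",
             "configuration_error")
  check_that(trial_duration > 0 && fs > 0,
             "durations and fs must be positive", "configuration_error")
  if (is.null(source_bands)) {
    base <- list(c(8, 12), c(8, 12), c(20, 24), c(20, 24))
    source_bands <- lapply(seq_len(n_classes), function(k) {
      base[[(k - 1L) %% 4L + 1L]]
    })
  }
  check_that(length(source_bands) == n_classes,
             "need one source band per class", "configuration_error")
  for (b in source_bands) {
    if (!(b[1] > 0 && b[2] > b[1] && b[2] < fs / 2)) {
      clfc_error(sprintf("source band (%s) must lie strictly inside (0, fs/2)",
                         paste(b, collapse = ", ")), "configuration_error")
    }
  }
  if (is.matrix(mixing_matrix)) {
    check_that(nrow(mixing_matrix) == n_channels &&
                 ncol(mixing_matrix) == n_classes,
               "mixing matrix must be [n_channels x n_classes]",
               "configuration_error")
    check_that(qr(mixing_matrix)$rank == n_classes,
               "mixing matrix must have full column rank",
               "configuration_error")
  } else {
    check_that(identical(mixing_matrix, "random-orthonormal"),
               "mixing_matrix must be a matrix or \"random-orthonormal\"",
               "configuration_error")
    check_that(n_channels >= n_classes,
               "random-orthonormal mixing needs n_channels >= n_classes",
               "configuration_error")
  }
  structure(list(n_classes = as.integer(n_classes),
                 trials_per_class = as.integer(trials_per_class),
                 n_channels = as.integer(n_channels), fs = fs,
                 trial_duration = trial_duration,
                 include_fixation = isTRUE(include_fixation),
                 fixation_duration = fixation_duration,
                 cue_duration = cue_duration,
                 source_bands = source_bands, class_gain = class_gain,
                 mixing_matrix = mixing_matrix, snr_db = snr_db,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "simulation_config")
}

# 1/f amplitude shaping of white noise columns
pink_noise_mat <- function(n, m) {
  w <- matrix(stats::rnorm(n * m), n, m)
  sp <- stats::mvfft(w)
  f <- c(1, seq_len(n - 1))            # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)              # fold to two-sided frequency index
  amp <- 1 / sqrt(f)
  x <- Re(stats::mvfft(sp * amp, inverse = TRUE)) / n
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/")
  x
}

#' Generate one synthetic epoched session
#'
#' Produces balanced labels and, for each class, a latent band-limited
#' source with elevated variance on that class's trials, mixed into the
#' channels plus noise at the configured SNR. The same seed gives a
#' bit-identical session.
#'
#' @param config A [simulation_config()].
#' @return An [eeg_recording()] with the generator's mixing matrix attached
#'   as attribute `mixing_matrix` (for parameter-recovery checks).
#' @export
generate_session <- function(config) {
  check_that(inherits(config, "simulation_config"),
             "config must be a simulation_config")
  set.seed(config$seed)
  fs <- config$fs
  k <- config$n_classes
  n_trials <- k * config$trials_per_class
  pre <- if (config$include_fixation)
    config$fixation_duration + config$cue_duration else 0
  n_pre <- round(pre * fs)
  n_mi <- round(config$trial_duration * fs)
  n_samp <- n_pre + n_mi
  labels <- rep(seq_len(k) - 1L, each = config$trials_per_class)

  if (is.matrix(config$mixing_matrix)) {
    mix <- config$mixing_matrix
  } else {
    mix <- qr.Q(qr(matrix(stats::rnorm(config$n_channels * k),
                          config$n_channels, k)))
  }

  # latent sources: band-passed white noise, unit sd, class gain on own trials
  sources <- array(0, c(n_trials, k, n_samp))
  mi_idx <- (n_pre + 1L):n_samp
  for (s in seq_len(k)) {
    bf <- signal::butter(4, config$source_bands[[s]] / (fs / 2), type = "pass")
    raw <- matrix(stats::rnorm(n_samp * n_trials), n_samp, n_trials)
    flt <- filtfilt_mat(bf$b, bf$a, raw, pad = min(n_samp - 1L, fs))
    flt <- sweep(flt, 2, apply(flt, 2, stats::sd), "/")
    gain <- rep(1, n_trials)
    gain[labels == (s - 1L)] <- config$class_gain
    # modulation acts on the imagery window only
    flt[mi_idx, ] <- sweep(flt[mi_idx, , drop = FALSE], 2, gain, "*")
    sources[, s, ] <- t(flt)
  }

  signals <- array(0, c(n_trials, config$n_channels, n_samp))
  snr <- 10^(config$snr_db / 10)
  noise_all <- if (config$noise_model == "pink") {
    pink_noise_mat(n_samp, n_trials * config$n_channels)
  } else {
    matrix(stats::rnorm(n_samp * n_trials * config$n_channels),
           n_samp, n_trials * config$n_channels)
  }
  for (i in seq_len(n_trials)) {
    src <- matrix(sources[i, , ], nrow = k)
    clean <- mix %*% src
    noise <- t(noise_all[, ((i - 1L) * config$n_channels + 1L):
                           (i * config$n_channels), drop = FALSE])
    p_sig <- mean(clean^2)
    p_noi <- mean(noise^2)
    signals[i, , ] <- clean + noise * sqrt(p_sig / (snr * p_noi))
  }

  class_names <- c("left", "right", "feet", "tongue")[seq_len(min(k, 4L))]
  if (k > 4L) class_names <- c(class_names, paste0("class", 5:k))
  rec <- eeg_recording(signals, labels, fs,
                       channel_names = if (config$n_channels == 22L)
                         mi22_channels() else NULL,
                       class_names = class_names,
                       trial_onset = if (config$include_fixation)
                         -config$fixation_duration else config$cue_duration)
  attr(rec, "mixing_matrix") <- mix
  attr(rec, "config") <- config
  rec
}
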
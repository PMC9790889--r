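# Hilbert-envelope extraction and unified-length resampling.
#
# The analytic signal is computed by the standard frequency-domain method
# (double the positive frequencies, zero the negative ones); its magnitude
# is the instantaneous amplitude. Envelopes are low-pass filtered at 4 Hz
# and resampled so that every analysis window, whatever its duration,
# contributes the same number of time points to the network input.

# complex analytic signal of matrix columns (frequency-domain method)
analytic_mat <- function(xm) {
  n <- nrow(xm)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::mvfft(stats::mvfft(xm) * h, inverse = TRUE) / n
}

#' Envelope of the analytic signal
#'
#' @param x Numeric vector, or a matrix whose columns are independent
#'   series (time down the rows); length must be at least 4.
#' @return Nonnegative envelope, same shape as `x`.
#' @export
analytic_envelope <- function(x) {
  vec <- is.null(dim(x))
  xm <- as.matrix(x)
  check_that(all(is.finite(xm)), "input contains NaN/Inf", "contract_error")
  check_that(nrow(xm) >= 4L, "need at least 4 samples", "contract_error")
  env <- Mod(analytic_mat(xm))
  if (vec) as.vector(env) else env
}

#' Anti-aliased resampling of an envelope to a fixed number of points
#'
#' Low-pass filters at `cutoff` Hz (zero-phase Butterworth) and then
#' samples exactly `n_points` values at window-centered time points, so
#' the output length is independent of the window duration. The implied
#' output rate `n_points / duration` must be at least twice the cutoff.
#'
#' @param env Envelope vector, or matrix with series in columns.
#' @param fs_in Input sampling rate in Hz.
#' @param n_points Target number of points (>= 2).
#' @param cutoff Envelope low-pass cutoff in Hz (default 4).
#' @param order Butterworth order of the anti-alias filter (default 4).
#' @return Resampled envelope (`n_points` rows), with the effective output
#'   rate attached as attribute `fs_out`.
#' @export
lowpass_resample <- function(env, fs_in, n_points, cutoff = 4, order = 4L) {
  vec <- is.null(dim(env))
  em <- as.matrix(env)
  n <- nrow(em)
  check_that(is_count(n_points, 2L), "n_points must be >= 2", "contract_error")
  duration <- n / fs_in
  fs_out <- n_points / duration
  if (fs_out < 2 * cutoff) {
    clfc_error(sprintf(
      "implied output rate %.3g Hz is below the Nyquist rate %g Hz for a %g Hz envelope",
      fs_out, 2 * cutoff, cutoff), "nyquist_error")
  }
  bf <- signal::butter(order, cutoff / (fs_in / 2), type = "low")
  sm <- zerophase_fft_mat(bf$b, bf$a, em,
                          pad = min(n - 1L, ceiling(fs_in / cutoff)))
  # vectorized linear interpolation at window-centered output times
  t_in <- (seq_len(n) - 0.5) / fs_in
  t_out <- (seq_len(n_points) - 0.5) * duration / n_points
  pos <- (t_out - t_in[1]) * fs_in + 1
  i0 <- pmin(pmax(floor(pos), 1L), n)
  i1 <- pmin(i0 + 1L, n)
  w1 <- pmin(pmax(pos - i0, 0), 1)
  out <- (1 - w1) * sm[i0, , drop = FALSE] + w1 * sm[i1, , drop = FALSE]
  attr(out, "fs_out") <- fs_out
  if (vec) {
    v <- as.vector(out)
    attr(v, "fs_out") <- fs_out
    v
  } else out
}

#' Envelope features for all projected (band, step) blocks
#'
#' Applies [analytic_envelope()] (with 10% reflective padding against
#' Hilbert edge artifacts) and [lowpass_resample()] to every spatially
#' filtered component, yielding a tensor with a unified time axis.
#'
#' @param projected A [project_msfbcsp()] result (`msfb_projected`).
#' @param n_points Unified number of time points per window (default 40).
#' @param cutoff Envelope low-pass cutoff in Hz (default 4).
#' @return Object of class `envelope_tensor`: array `values`
#'   `[trials, bands, steps, components, n_points]` plus per-step output
#'   rates.
#' @export
envelope_pipeline <- function(projected, n_points = 40L, cutoff = 4) {
  check_that(inherits(projected, "msfb_projected"),
             "projected must come from project_msfbcsp()")
  nb <- projected$n_bands; nt <- projected$n_steps
  ntr <- projected$n_trials; nc <- projected$n_components
  vals <- array(0, c(ntr, nb, nt, nc, n_points))
  fs_out <- numeric(nt)
  for (bi in seq_len(nb)) {
    for (ti in seq_len(nt)) {
      blk <- projected$blocks[[bi]][[ti]]
      len <- dim(blk)[3]
      # series in columns: [samples x (trials*components)]
      xm <- matrix(aperm(blk, c(3, 1, 2)), nrow = len)
      pd <- good_fft_pad(len, max(4L, round(0.1 * len)))
      xp <- reflect_pad(xm, pd$left, pd$right)
      env <- analytic_envelope(xp)[(pd$left + 1L):(pd$left + len), ,
                                   drop = FALSE]
      res <- lowpass_resample(env, projected$fs, n_points, cutoff = cutoff)
      fs_out[ti] <- attr(res, "fs_out")
      vals[, bi, ti, , ] <- aperm(array(res, c(n_points, ntr, nc)),
                                  c(2, 3, 1))
    }
  }
  structure(list(values = vals, n_points = as.integer(n_points),
                 fs_out = fs_out, bands = projected$bands,
                 intervals = projected$intervals),
            class = "envelope_tensor")
}

#' Flatten an envelope tensor into network input
#'
#' Reshapes `[trials, bands, steps, components, points]` into the
#' components-by-time layout the network consumes:
#' `[trials, bands*steps*components, points]`.
#'
#' @param env_tensor An [envelope_pipeline()] result.
#' @return 3-d array `[trials, channels, points]`.
#' @export
envelope_to_input <- function(env_tensor) {
  check_that(inherits(env_tensor, "envelope_tensor"),
             "need an envelope_tensor")
  v <- env_tensor$values
  d <- dim(v)
  out <- aperm(v, c(1, 4, 3, 2, 5))   # trials, comp, step, band, points
  dim(out) <- c(d[1], d[2] * d[3] * d[4], d[5])
  out
}
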
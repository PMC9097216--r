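#' Anti-aliased integer-factor downsampling
#'
#' Low-pass filters with a zero-phase windowed-sinc FIR (cut-off at the output
#' Nyquist rate) before keeping every `fs_in/fs_out`-th sample, so sensor
#' noise above the output Nyquist cannot alias into the sway band.
#'
#' @param x Numeric series.
#' @param fs_in,fs_out Input and output sampling rates; `fs_in` must be an
#'   integer multiple of `fs_out`.
#' @return Numeric series of length `floor(length(x) / factor)`.
#' @export
downsample <- function(x, fs_in, fs_out) {
  if (fs_in <= 0 || fs_out <= 0) abort("sampling rates must be positive")
  factor <- fs_in / fs_out
  if (abs(factor - round(factor)) > 1e-9) {
    abort(sprintf("fs_in (%g) must be an integer multiple of fs_out (%g)", fs_in, fs_out))
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(x)
  n <- length(x)
  # long windowed-sinc FIR: transition narrow enough that the passband stays
  # flat to well within 1% up to ~0.8 * Nyquist_out; linear phase makes a
  # single centered pass exactly zero-phase
  ntaps <- min(60L * factor, n - 1L)
  if (ntaps %% 2L == 1L) ntaps <- ntaps - 1L
  if (ntaps < 8L) abort("input too short to anti-alias filter")
  b <- signal::fir1(ntaps, 1 / factor, type = "low")
  d <- ntaps %/% 2L
  # odd-reflection padding, then exact linear convolution via FFT
  xp <- c(2 * x[1] - x[(d + 1):2], x, 2 * x[n] - x[(n - 1):(n - d)])
  nfft <- stats::nextn(length(xp) + length(b) - 1L)
  y <- Re(fft(fft(c(xp, numeric(nfft - length(xp)))) *
                fft(c(b, numeric(nfft - length(b)))), inverse = TRUE)) / nfft
  y <- y[(2L * d + 1L):(2L * d + n)]
  y[seq.int(1L, n, by = factor)][seq_len(floor(n / factor))]
}

#' Crop the central portion of a series
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param keep_s Seconds to keep, centered.
#' @return A contiguous block of exactly `keep_s * fs` samples.
#' @export
crop_middle <- function(x, fs, keep_s) {
  keep <- as.integer(round(keep_s * fs))
  if (length(x) < keep) {
    abort(sprintf("need >= %d samples to crop %g s at %g Hz, got %d",
                  keep, keep_s, fs, length(x)))
  }
  start <- floor((length(x) - keep) / 2)
  x[(start + 1L):(start + keep)]
}

#' Tilt-correct a tri-axial recording to the anatomical frame
#'
#' A trunk sensor is never mounted perfectly level, so gravity leaks into the
#' horizontal channels. Under the quiet-stance assumption the per-trial mean
#' acceleration vector estimates gravity in the sensor frame; two sequential
#' rotations (about the ML axis to null the mean AP component, then about the
#' updated AP axis to null the mean ML component) re-align the vertical axis
#' with gravity. The corrected ML and AP series then have zero mean by
#' construction; the vertical channel is discarded.
#'
#' @param acc Data frame with columns `ml`, `ap`, `vert` (m s^-2).
#' @param g Gravitational acceleration used for the plausibility check.
#' @return Tibble with zero-mean columns `ml` and `ap`.
#' @export
tilt_correct <- function(acc, g = 9.81) {
  acc <- as_tibble(acc)
  m <- c(mean(acc$ml), mean(acc$ap), mean(acc$vert))
  mag <- sqrt(sum(m^2))
  if (mag == 0) abort("zero-magnitude mean acceleration: cannot estimate gravity")
  if (abs(mag - g) > 0.2 * g) {
    warn(sprintf("mean acceleration magnitude %.2f m/s^2 departs >20%% from g", mag))
  }
  # rotation about ML (x) axis nulls the mean AP component
  theta <- atan2(m[2], m[3])
  rot_x <- rbind(c(1, 0, 0),
                 c(0, cos(theta), -sin(theta)),
                 c(0, sin(theta), cos(theta)))
  # after it, rotation about AP (y) axis nulls the mean ML component
  m1 <- rot_x %*% m
  phi <- atan2(m1[1], m1[3])
  rot_y <- rbind(c(cos(phi), 0, -sin(phi)),
                 c(0, 1, 0),
                 c(sin(phi), 0, cos(phi)))
  rot <- rot_y %*% rot_x
  xyz <- rbind(acc$ml, acc$ap, acc$vert)
  out <- rot %*% xyz
  # the chosen angles null the mean ML and AP components exactly
  tibble(ml = out[1, ], ap = out[2, ])
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of order `order` and applies it forward and
#' backward (`filtfilt`), cancelling phase distortion at the cost of squaring
#' the magnitude response.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param low,high Pass-band corner frequencies, Hz.
#' @param order Order of the band-pass transfer function (even).
#' @return Filtered series, same length.
#' @export
bandpass <- function(x, fs, low = 0.3, high = 10, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort("need 0 < low < high < fs/2")
  }
  if (order < 2 || order %% 2 != 0) abort("order must be an even integer >= 2")
  bw <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  n <- length(x)
  # de-mean, then odd-reflection padding: keeps the forward-backward pass
  # free of edge transients (the filter rejects DC exactly, so the mean
  # carries no information)
  xm <- x - mean(x)
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / low)))
  ext <- c(2 * xm[1] - xm[(pad + 1):2], xm, 2 * xm[n] - xm[(n - 1):(n - pad)])
  y <- signal::filtfilt(bw, ext)[(pad + 1):(pad + n)]
  y - mean(y)
}

#' Resultant horizontal acceleration magnitude
#'
#' @param ml,ap Equal-length ML and AP series.
#' @return Elementwise `sqrt(ml^2 + ap^2)`.
#' @export
resultant <- function(ml, ap) {
  if (length(ml) != length(ap)) abort("ml and ap must have equal length")
  sqrt(ml^2 + ap^2)
}

#' Windowed standard-deviation artifact screen
#'
#' Splits the resultant horizontal acceleration into consecutive
#' non-overlapping windows and compares the spread of their standard
#' deviations: the trial fails when the largest window SD strictly exceeds
#' `ratio_max` times the smallest, flagging transient behaviour (steps,
#' bumps, signal dropouts) that a quiet-stance trial must not contain.
#'
#' @param res Resultant series (see [resultant()]).
#' @param fs Sampling rate, Hz.
#' @param n_windows,window_s Number and duration (s) of the windows; their
#'   product times `fs` must equal `length(res)`.
#' @param ratio_max Largest tolerated max/min SD ratio (boundary passes).
#' @return A tibble with one row: `pass`, `ratio`, and a list-column
#'   `window_sds`.
#' @export
artifact_screen <- function(res, fs, n_windows = 5, window_s = 10, ratio_max = 5.0) {
  expected <- as.integer(round(n_windows * window_s * fs))
  if (length(res) != expected) {
    abort(sprintf("expected %d samples (%d windows x %g s x %g Hz), got %d",
                  expected, n_windows, window_s, fs, length(res)))
  }
  idx <- rep(seq_len(n_windows), each = expected / n_windows)
  sds <- vapply(split(res, idx), sd, numeric(1))
  ratio <- max(sds) / min(sds)
  tibble(pass = ratio <= ratio_max, ratio = ratio, window_sds = list(unname(sds)))
}

#' Preprocess one raw trial into analysis-ready ML and AP signals
#'
#' Runs the full preprocessing chain in protocol order: anti-aliased
#' downsampling to `cfg$fs_target`, central `cfg$crop_s` crop, tilt-correction
#' to the anatomical frame, zero-phase band-pass, then the artifact screen on
#' the resultant of the filtered pair. Failing trials are flagged in the
#' verdict, never silently dropped.
#'
#' @param rec A [sway_recording()].
#' @param cfg A [sway_config()].
#' @return A list with tibble `signals` (columns `ml`, `ap`, `fs` attribute via
#'   `fs` element), the `verdict` row from [artifact_screen()], and the trial
#'   `meta`.
#' @export
preprocess_trial <- function(rec, cfg = sway_config()) {
  stopifnot(inherits(rec, "sway_recording"))
  ds <- lapply(rec$acc, downsample, fs_in = rec$fs_in, fs_out = cfg$fs_target)
  cropped <- lapply(ds, crop_middle, fs = cfg$fs_target, keep_s = cfg$crop_s)
  anat <- tilt_correct(as_tibble(cropped))
  filt <- tibble(
    ml = bandpass(anat$ml, cfg$fs_target, cfg$band[1], cfg$band[2], cfg$filter_order),
    ap = bandpass(anat$ap, cfg$fs_target, cfg$band[1], cfg$band[2], cfg$filter_order)
  )
  verdict <- artifact_screen(resultant(filt$ml, filt$ap), cfg$fs_target,
                             cfg$artifact_windows, cfg$artifact_window_s,
                             cfg$artifact_ratio)
  list(signals = filt, fs = cfg$fs_target, verdict = verdict, meta = rec$meta)
}
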
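#' Construct a pupil-diameter epoch
#'
#' @param t Timestamps in seconds.
#' @param diameter Pupil diameter in mm.
#' @param eye `"left"` or `"right"`.
#' @param fs Nominal sampling rate in Hz.
#' @param valid Logical validity flags (blinks / tracking loss = `FALSE`).
#' @param id Optional epoch identifier.
#' @return An object of class `pupil_epoch`.
#' @export
pupil_epoch <- function(t, diameter, eye = c("left", "right"),
                        fs = 1 / stats::median(diff(t)),
                        valid = rep(TRUE, length(t)), id = NULL) {
  eye <- match.arg(eye)
  stopifnot(length(t) == length(diameter), length(valid) == length(t))
  structure(list(t = as.numeric(t), diameter = as.numeric(diameter),
                 valid = as.logical(valid), eye = eye, fs = fs, id = id),
            class = "pupil_epoch")
}

#' Extract left/right pupil epochs from a gaze recording
#'
#' @param gaze A gaze [cwl_ts] (schema `gaze`).
#' @param eye `"left"` or `"right"`.
#' @param id Optional epoch identifier.
#' @return A `pupil_epoch`.
#' @export
pupil_from_gaze <- function(gaze, eye = c("left", "right"), id = NULL) {
  eye <- match.arg(eye)
  ch <- if (eye == "left") "pupil_left_mm" else "pupil_right_mm"
  s <- ts_channel(gaze, ch)
  pupil_epoch(s$t, s$value, eye, fs = gaze$fs, valid = s$valid, id = id)
}

.check_uniform <- function(t, fs, tol = 0.01) {
  dt <- diff(t)
  if (length(dt) && max(abs(dt - 1 / fs)) > tol / fs) {
    stop("epoch is not uniformly sampled; resample first", call. = FALSE)
  }
}

#' Blink / dropout preprocessing for pupil epochs
#'
#' Epochs with fewer than `min_valid` valid samples are rejected
#' (a classed error, condition class `cwl_epoch_rejected`, carrying the
#' reason). Invalid runs up to `max_gap` seconds are bridged by linear
#' interpolation -- the usual treatment for blinks, which rarely exceed
#' ~400 ms. Longer invalid runs split the epoch; invalid samples at the
#' edges are trimmed. Each surviving piece is resampled to `fs` so the
#' spectral metrics see uniform sampling.
#'
#' @param epoch A `pupil_epoch`.
#' @param max_gap Longest invalid run (s) to interpolate across
#'   (default 0.5).
#' @param min_valid Minimum fraction of valid samples (default 0.5).
#' @return A list of fully valid, uniformly sampled `pupil_epoch` pieces
#'   (length 1 when no long gap splits the epoch).
#' @export
preprocess_pupil <- function(epoch, max_gap = 0.5, min_valid = 0.5) {
  stopifnot(inherits(epoch, "pupil_epoch"))
  ok <- epoch$valid & is.finite(epoch$diameter) & epoch$diameter > 0
  frac <- mean(ok)
  if (frac < min_valid) {
    stop(structure(class = c("cwl_epoch_rejected", "error", "condition"),
                   list(message = sprintf(
                     "epoch rejected: only %.0f%% valid samples (need >= %.0f%%)",
                     100 * frac, 100 * min_valid),
                     call = NULL)))
  }
  # split points: invalid runs longer than max_gap
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- 1 / epoch$fs
  long_gap <- !r$values & (r$lengths * dt) > max_gap
  piece_bounds <- list()
  piece_start <- 1L
  for (i in seq_along(r$lengths)) {
    if (long_gap[i]) {
      piece_bounds[[length(piece_bounds) + 1L]] <- c(piece_start, starts[i] - 1L)
      piece_start <- ends[i] + 1L
    }
  }
  piece_bounds[[length(piece_bounds) + 1L]] <- c(piece_start, length(ok))
  pieces <- list()
  for (b in piece_bounds) {
    if (b[2] < b[1]) next
    idx <- seq.int(b[1], b[2])
    # trim invalid edges
    v <- ok[idx]
    if (!any(v)) next
    idx <- idx[seq.int(which(v)[1], max(which(v)))]
    tt <- epoch$t[idx]
    d <- epoch$diameter[idx]
    vv <- ok[idx]
    # bridge the short gaps
    if (any(!vv)) d[!vv] <- stats::approx(tt[vv], d[vv], xout = tt[!vv])$y
    grid <- seq(tt[1], tt[length(tt)], by = 1 / epoch$fs)
    dg <- stats::approx(tt, d, xout = grid)$y
    pieces[[length(pieces) + 1L]] <-
      pupil_epoch(grid, dg, epoch$eye, fs = epoch$fs, id = epoch$id)
  }
  pieces
}

#' L1 norm of the pupil-diameter spectrum (L1NS)
#'
#' The workload index obtained by summing the single-sided FFT amplitude
#' spectrum of the mean-subtracted pupil-diameter series over the 1-5 Hz
#' band (inclusive). Task-evoked pupil dynamics concentrate in this band,
#' above slow luminance-driven drift (< 0.2 Hz) and below tracker noise,
#' so the index rises with cognitive load while staying insensitive to
#' ambient-light changes.
#'
#' Scaling: amplitudes are `2 |Y_j| / N` for interior bins (DC and
#' Nyquist unscaled by the factor 2), so a sinusoid of amplitude `a`
#' landing on a bin contributes `a` to the sum.
#'
#' The default Hann taper matters here: slow drift that is not an
#' integer number of periods long leaks through the 1/f sidelobes of a
#' rectangular window into every 1-5 Hz bin, and summed over ~40 bins
#' that leakage can exceed the band signal itself. The Hann taper's
#' fast-decaying sidelobes keep sub-0.2 Hz luminance drift out of the
#' band, and because the taper is applied without coherent-gain
#' renormalisation, the *band sum* of a bin-aligned sinusoid of
#' amplitude `a` is still exactly `a` (peak bin `a/2` plus two
#' neighbours of `a/4`).
#'
#' @param epoch A uniformly sampled `pupil_epoch` of at least 2 s.
#' @param band Analysis band in Hz, default `c(1, 5)`.
#' @param window `"hann"` (default, see above) or `"none"` (raw
#'   epoch-length rectangular FFT).
#' @return The band amplitude sum in mm.
#' @export
l1ns <- function(epoch, band = c(1, 5), window = c("hann", "none")) {
  stopifnot(inherits(epoch, "pupil_epoch"))
  window <- match.arg(window)
  .check_uniform(epoch$t, epoch$fs)
  n <- length(epoch$diameter)
  dur <- (n - 1) / epoch$fs
  if (dur < 2) stop("epoch too short for L1NS (< 2 s)", call. = FALSE)
  if (epoch$fs <= 2 * band[2]) {
    stop("sampling rate must exceed twice the upper band edge", call. = FALSE)
  }
  y <- epoch$diameter - mean(epoch$diameter)
  if (window == "hann") {
    # no coherent-gain renormalisation: keeps the band SUM of a
    # bin-aligned sinusoid equal to its amplitude
    y <- y * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
  sp <- single_sided_amplitude(y, epoch$fs)
  sum(sp$amplitude[sp$freq >= band[1] & sp$freq <= band[2]])
}

#' Single-sided amplitude spectrum
#'
#' @param y Numeric signal (uniformly sampled).
#' @param fs Sampling rate (Hz).
#' @return Data frame with `freq` (Hz) and `amplitude` (signal units):
#'   `2|Y|/N` at interior bins, `|Y|/N` at DC and (even `N`) Nyquist.
#' @export
single_sided_amplitude <- function(y, fs) {
  n <- length(y)
  Y <- stats::fft(y)
  half <- floor(n / 2) + 1L
  amp <- Mod(Y[seq_len(half)]) / n
  if (half > 2) {
    interior <- 2:(half - 1L)
    amp[interior] <- 2 * amp[interior]
    if (n %% 2 == 1) amp[half] <- 2 * amp[half]  # no Nyquist bin for odd n
  }
  data.frame(freq = (seq_len(half) - 1) * fs / n, amplitude = amp)
}

#' Standard deviation of pupil diameter (STDP)
#'
#' @param epoch A `pupil_epoch` with at least 2 samples.
#' @return Sample standard deviation (n - 1 denominator) in mm.
#' @export
stdp <- function(epoch) {
  stopifnot(inherits(epoch, "pupil_epoch"))
  if (length(epoch$diameter) < 2) stop("need at least 2 samples", call. = FALSE)
  stats::sd(epoch$diameter)
}

#' Low-pass-filter pupil metric (LPF)
#'
#' Mean absolute value of the zero-phase low-pass-filtered, mean-subtracted
#' pupil-diameter signal: a time-domain companion to [l1ns] that captures
#' slow task-evoked dilation. Butterworth design, applied forward and
#' backward ([signal::filtfilt]) so the filter adds no phase lag.
#'
#' @param epoch A uniformly sampled `pupil_epoch`.
#' @param cutoff Low-pass cutoff in Hz (default 4, inside the 1-5 Hz
#'   analysis band).
#' @param order Butterworth order (default 4).
#' @return Mean absolute filtered deviation, mm.
#' @export
lpf_metric <- function(epoch, cutoff = 4, order = 4) {
  stopifnot(inherits(epoch, "pupil_epoch"))
  .check_uniform(epoch$t, epoch$fs)
  if (cutoff >= epoch$fs / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  y <- epoch$diameter - mean(epoch$diameter)
  if (max(abs(y)) == 0) return(0)
  bf <- signal::butter(order, cutoff / (epoch$fs / 2), type = "low")
  yf <- signal::filtfilt(bf, y)
  mean(abs(yf))
}
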
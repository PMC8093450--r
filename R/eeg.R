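#' Canonical EEG frequency bands
#'
#' The five-band partition used throughout: theta 4-8 Hz, alpha 8-13 Hz,
#' low beta 13-21 Hz, high beta 21-30 Hz, gamma 31-100 Hz. Band powers in
#' theta through high beta rise with task demand; gamma is excluded from
#' default summaries because consumer headsets sample too slowly to cover
#' it and it showed no demand sensitivity.
#'
#' @param include_gamma Include the gamma band row? Default `FALSE`.
#' @return Data frame with columns `band`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function(include_gamma = FALSE) {
  b <- data.frame(band = c("theta", "alpha", "low_beta", "high_beta", "gamma"),
                  lo = c(4, 8, 13, 21, 31),
                  hi = c(8, 13, 21, 30, 100),
                  stringsAsFactors = FALSE)
  if (include_gamma) b else b[b$band != "gamma", ]
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is split into
#' `window_s`-second Hann-tapered segments overlapping by `overlap`, each
#' segment is mean-subtracted, and the one-sided periodograms (scaled to
#' density, units^2/Hz) are averaged. Frequency resolution is
#' `1 / window_s`.
#'
#' @param x Numeric signal, uniformly sampled.
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return Data frame of class `cwl_psd` with columns `freq` (Hz) and
#'   `psd` (units^2/Hz); attributes `fs`, `df` and `enbw`.
#' @export
psd_welch <- function(x, fs, window_s = 2, overlap = 0.5) {
  x <- as.numeric(x)
  nwin <- round(window_s * fs)
  if (length(x) < nwin) {
    stop("signal shorter than one Welch window", call. = FALSE)
  }
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nwin) - 1) / (nwin - 1))  # Hann
  scale <- fs * sum(w^2)
  half <- floor(nwin / 2) + 1L
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg)[seq_len(half)])^2 / scale
    p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]
    if (nwin %% 2 == 1) p[half] <- 2 * p[half]
    acc <- acc + p
  }
  out <- data.frame(freq = (seq_len(half) - 1) * fs / nwin,
                    psd = acc / length(starts))
  attr(out, "fs") <- fs
  attr(out, "df") <- fs / nwin
  attr(out, "enbw") <- fs * sum(w^2) / sum(w)^2
  class(out) <- c("cwl_psd", "data.frame")
  out
}

#' Integrated band power from a PSD
#'
#' Trapezoidal integral of the power spectral density over `[lo, hi]`.
#' Bands reaching above the Nyquist frequency are clipped with a warning
#' (relevant for gamma at 128 Hz sampling); bands lying entirely above
#' Nyquist are an error.
#'
#' @param spectrum A `cwl_psd` from [psd_welch].
#' @param band A band name from [eeg_bands()], or a numeric `c(lo, hi)`
#'   in Hz.
#' @return Band power in units^2 (microvolts^2 for EEG).
#' @export
band_power <- function(spectrum, band) {
  if (is.character(band)) {
    tab <- eeg_bands(include_gamma = TRUE)
    row <- tab[tab$band == band, ]
    if (!nrow(row)) stop(sprintf("unknown band '%s'", band), call. = FALSE)
    band <- c(row$lo, row$hi)
  }
  lo <- band[1]; hi <- band[2]
  stopifnot(lo < hi)
  fmax <- max(spectrum$freq)
  if (lo >= fmax) {
    stop(sprintf("band [%g, %g] lies entirely above the Nyquist frequency %g",
                 lo, hi, fmax), call. = FALSE)
  }
  if (hi > fmax) {
    warning(sprintf("band [%g, %g] clipped at Nyquist %g Hz", lo, hi, fmax),
            call. = FALSE)
    hi <- fmax
  }
  f <- spectrum$freq
  p <- spectrum$psd
  # interpolate the exact edges so the integral covers [lo, hi] precisely
  sel <- f > lo & f < hi
  fg <- c(lo, f[sel], hi)
  pg <- c(stats::approx(f, p, xout = lo)$y, p[sel],
          stats::approx(f, p, xout = hi)$y)
  sum(diff(fg) * (utils::head(pg, -1) + utils::tail(pg, -1)) / 2)
}

#' Band-power summary of a multi-channel EEG recording
#'
#' Splits each channel into consecutive epochs of `epoch_s` seconds,
#' estimates a Welch PSD per epoch, integrates each band, and pools the
#' per-channel, per-epoch powers into one median per band (channels and
#' epochs pooled, then the median taken), matching the single
#' median-per-band summary reported per condition.
#'
#' @param recording A [cwl_ts] with one column per EEG channel.
#' @param bands Band table as from [eeg_bands()].
#' @param epoch_s Epoch length in seconds (default 10; clipped to the
#'   recording length).
#' @param window_s,overlap Welch parameters, see [psd_welch].
#' @return List with `powers` (long data frame `channel`, `epoch`,
#'   `band`, `power`) and `median` (data frame `band`, `power`).
#' @export
band_power_summary <- function(recording, bands = eeg_bands(),
                               epoch_s = 10, window_s = 2, overlap = 0.5) {
  stopifnot(inherits(recording, "cwl_ts"))
  fs <- recording$fs
  chans <- names(recording$values)
  usable <- chans[vapply(chans, function(ch) {
    v <- recording$values[[ch]]
    any(recording$valid[[ch]] & is.finite(v))
  }, logical(1))]
  if (!length(usable)) stop("no valid EEG channel", call. = FALSE)
  nsamp <- length(recording$t)
  epoch_n <- min(round(epoch_s * fs), nsamp)
  if (epoch_n < round(window_s * fs)) epoch_n <- nsamp
  starts <- seq(1L, nsamp - epoch_n + 1L, by = epoch_n)
  chan_v <- character(); epoch_v <- integer(); band_v <- character()
  power_v <- numeric()
  for (ch in usable) {
    v <- recording$values[[ch]]
    for (e in seq_along(starts)) {
      seg <- v[starts[e]:(starts[e] + epoch_n - 1L)]
      if (anyNA(seg)) next
      sp <- psd_welch(seg, fs, window_s, overlap)
      for (b in seq_len(nrow(bands))) {
        chan_v <- c(chan_v, ch); epoch_v <- c(epoch_v, e)
        band_v <- c(band_v, bands$band[b])
        power_v <- c(power_v,
                     band_power(sp, c(bands$lo[b],
                                      min(bands$hi[b], max(sp$freq)))))
      }
    }
  }
  powers <- data.frame(channel = chan_v, epoch = epoch_v, band = band_v,
                       power = power_v)
  med <- stats::aggregate(power ~ band, data = powers, FUN = stats::median)
  med <- med[match(bands$band, med$band), ]
  rownames(med) <- NULL
  list(powers = powers, median = med)
}
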
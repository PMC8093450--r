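#' Multi-channel time series
#'
#' The substrate of every recording handled by cogload: a vector of
#' timestamps in seconds, one or more named channels, and a per-sample,
#' per-channel validity flag. Units are carried as an attribute per
#' channel (mm for pupil diameter, degrees for gaze angles, microvolts
#' for EEG, mm for inceptor deflection, ft/knots for flight state).
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param values Data frame of channel values, one row per timestamp.
#' @param valid Optional logical data frame of the same shape as `values`
#'   (`TRUE` = sample usable). Defaults to everything valid.
#' @param fs Nominal sampling rate in Hz. Defaults to `1 / median(diff(t))`.
#' @param units Optional named character vector of channel units.
#' @return An object of class `cwl_ts`.
#' @export
cwl_ts <- function(t, values, valid = NULL, fs = NULL, units = NULL) {
  values <- as.data.frame(values)
  if (length(t) != nrow(values)) {
    stop("length(t) must equal the number of rows of `values`", call. = FALSE)
  }
  if (anyNA(t)) stop("timestamps must not be NA", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    stop(sprintf("timestamps must be strictly increasing (violation at row %d)", bad),
         call. = FALSE)
  }
  if (is.null(valid)) {
    valid <- as.data.frame(matrix(TRUE, nrow(values), ncol(values)))
    names(valid) <- names(values)
  } else {
    valid <- as.data.frame(valid)
    stopifnot(nrow(valid) == nrow(values), ncol(valid) == ncol(values))
    names(valid) <- names(values)
  }
  if (is.null(fs)) {
    fs <- if (length(t) > 1) 1 / stats::median(diff(t)) else NA_real_
  }
  structure(list(t = as.numeric(t), values = values, valid = valid,
                 fs = fs, units = units),
            class = "cwl_ts")
}

#' @export
print.cwl_ts <- function(x, ...) {
  cat(sprintf("<cwl_ts> %d samples, %.6g-%.6g s, %d channel(s) [%s], fs ~ %.4g Hz\n",
              length(x$t), min(x$t), max(x$t), ncol(x$values),
              paste(names(x$values), collapse = ", "), x$fs))
  invisible(x)
}

#' Duration of a time series in seconds
#' @param x A `cwl_ts`.
#' @return Elapsed time between the first and last sample, in seconds.
#' @export
ts_duration <- function(x) {
  stopifnot(inherits(x, "cwl_ts"))
  diff(range(x$t))
}

#' Extract one channel of a time series
#' @param x A `cwl_ts`.
#' @param channel Channel name.
#' @param valid_only Drop samples flagged invalid?
#' @return List with `t`, `value`, `valid`.
#' @export
ts_channel <- function(x, channel, valid_only = FALSE) {
  stopifnot(inherits(x, "cwl_ts"))
  if (!channel %in% names(x$values)) {
    stop(sprintf("no channel '%s' in time series", channel), call. = FALSE)
  }
  v <- x$values[[channel]]
  ok <- x$valid[[channel]]
  if (valid_only) list(t = x$t[ok], value = v[ok], valid = rep(TRUE, sum(ok)))
  else list(t = x$t, value = v, valid = ok)
}

#' Resample a time series onto a uniform grid
#'
#' Linear interpolation over valid samples onto `seq(min(t), max(t), by 1/fs)`.
#' Downstream spectral estimators (FFT amplitude spectra, Welch PSD) assume
#' uniform sampling, so resampling lives here rather than in each metric.
#' Samples that fall inside an invalid run remain flagged invalid.
#'
#' @param x A `cwl_ts`.
#' @param fs Target sampling rate (Hz); defaults to the nominal rate of `x`.
#' @return A uniformly sampled `cwl_ts`.
#' @export
ts_resample <- function(x, fs = x$fs) {
  stopifnot(inherits(x, "cwl_ts"), is.finite(fs), fs > 0)
  tt <- seq(min(x$t), max(x$t), by = 1 / fs)
  vals <- lapply(names(x$values), function(ch) {
    ok <- x$valid[[ch]] & is.finite(x$values[[ch]])
    if (sum(ok) < 2) return(rep(NA_real_, length(tt)))
    stats::approx(x$t[ok], x$values[[ch]][ok], xout = tt, rule = 2)$y
  })
  names(vals) <- names(x$values)
  valid <- lapply(names(x$values), function(ch) {
    ok <- x$valid[[ch]] & is.finite(x$values[[ch]])
    if (sum(ok) < 2) return(rep(FALSE, length(tt)))
    # a resampled point is valid if its nearest original neighbour was valid
    idx <- findInterval(tt, x$t, all.inside = TRUE)
    near <- ifelse(abs(tt - x$t[idx]) <= abs(x$t[pmin(idx + 1, length(x$t))] - tt),
                   idx, pmin(idx + 1, length(x$t)))
    ok[near]
  })
  names(valid) <- names(x$values)
  cwl_ts(tt, as.data.frame(vals), as.data.frame(valid), fs = fs, units = x$units)
}
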
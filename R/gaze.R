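#' I-VT velocity-threshold fixation classification
#'
#' Classifies each valid gaze sample as saccade (angular velocity at or
#' above `velocity_threshold`) or fixation, merges consecutive fixation
#' samples into fixation events, and discards fixations shorter than
#' `min_fixation` seconds. Velocity is the central difference over valid
#' neighbours (one-sided at epoch edges and next to invalid samples);
#' invalid samples break fixations.
#'
#' @param gaze A gaze [cwl_ts] with channels `gaze_x_deg`, `gaze_y_deg`.
#' @param velocity_threshold Saccade threshold in deg/s (default 30, the
#'   common I-VT default).
#' @param min_fixation Minimum fixation duration in seconds (default 0.06).
#' @return An object of class `cwl_fixations`: list with
#'   `fixations` (data frame `start`, `end`, `fx`, `fy`, `duration`),
#'   `saccades` (data frame `start`, `end`, `duration`),
#'   `n` (fixation count), `area` (deg^2, bounding rectangle of the valid
#'   gaze coordinates), `duration` (s, epoch span),
#'   `sample_class` (per-sample factor: fixation / saccade / discarded /
#'   invalid) and `dt` (s per sample).
#' @export
ivt_classify <- function(gaze, velocity_threshold = 30, min_fixation = 0.06) {
  stopifnot(inherits(gaze, "cwl_ts"))
  t <- gaze$t
  x <- gaze$values$gaze_x_deg
  y <- gaze$values$gaze_y_deg
  ok <- gaze$valid$gaze_x_deg & gaze$valid$gaze_y_deg &
    is.finite(x) & is.finite(y)
  n <- length(t)
  if (!any(ok)) {
    warning("all gaze samples invalid; empty fixation set", call. = FALSE)
    return(structure(list(
      fixations = data.frame(start = numeric(), end = numeric(),
                             fx = numeric(), fy = numeric(),
                             duration = numeric()),
      saccades = data.frame(start = numeric(), end = numeric(),
                            duration = numeric()),
      n = 0L, area = 0, duration = if (n > 1) diff(range(t)) else 0,
      sample_class = factor(rep("invalid", n),
                            levels = c("fixation", "saccade", "discarded", "invalid")),
      dt = if (n > 1) stats::median(diff(t)) else NA_real_),
      class = "cwl_fixations"))
  }
  # per-sample angular velocity: central difference over valid neighbours
  vel <- rep(NA_real_, n)
  for (i in which(ok)) {
    lo <- if (i > 1 && ok[i - 1]) i - 1L else i
    hi <- if (i < n && ok[i + 1]) i + 1L else i
    if (hi == lo) next
    vel[i] <- sqrt((x[hi] - x[lo])^2 + (y[hi] - y[lo])^2) / (t[hi] - t[lo])
  }
  vel[ok & is.na(vel)] <- 0  # isolated valid sample: no motion measurable
  cls <- rep("invalid", n)
  cls[ok & vel < velocity_threshold] <- "fixation"
  cls[ok & vel >= velocity_threshold] <- "saccade"
  dt <- stats::median(diff(t))

  runs <- rle(cls)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  durs <- runs$lengths * dt
  is_fix <- runs$values == "fixation"
  short <- is_fix & durs < min_fixation
  for (i in which(short)) cls[starts[i]:ends[i]] <- "discarded"
  keep_fix <- which(is_fix & !short)
  keep_sac <- which(runs$values == "saccade")
  fixations <- data.frame(
    start = t[starts[keep_fix]], end = t[ends[keep_fix]],
    fx = vapply(keep_fix, function(i) mean(x[starts[i]:ends[i]]), numeric(1)),
    fy = vapply(keep_fix, function(i) mean(y[starts[i]:ends[i]]), numeric(1)),
    duration = durs[keep_fix])
  saccades <- data.frame(start = t[starts[keep_sac]],
                         end = t[ends[keep_sac]],
                         duration = durs[keep_sac])
  area <- diff(range(x[ok])) * diff(range(y[ok]))
  structure(list(fixations = fixations, saccades = saccades,
                 n = nrow(fixations), area = area,
                 duration = diff(range(t)),
                 sample_class = factor(cls, levels = c("fixation", "saccade",
                                                       "discarded", "invalid")),
                 dt = dt),
            class = "cwl_fixations")
}

#' @export
print.cwl_fixations <- function(x, ...) {
  cat(sprintf("<cwl_fixations> %d fixations, %d saccades over %.3g s (area %.4g deg^2)\n",
              x$n, nrow(x$saccades), x$duration, x$area))
  invisible(x)
}

#' Fixation rate: fraction of time spent in fixations
#'
#' @param fixations A `cwl_fixations` object (or data frame with a
#'   `duration` column).
#' @param duration Epoch duration in seconds; defaults to the epoch span
#'   recorded in the fixation set.
#' @return Total fixation time divided by `duration`, in `[0, 1]`.
#' @export
fixation_rate <- function(fixations, duration = NULL) {
  fx <- if (inherits(fixations, "cwl_fixations")) fixations$fixations else fixations
  if (is.null(duration) && inherits(fixations, "cwl_fixations")) {
    duration <- fixations$duration
  }
  if (is.null(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  if (!nrow(fx)) return(0)
  min(sum(fx$duration) / duration, 1)
}

#' Saccade rate in events per second
#'
#' @param saccades A `cwl_fixations` object or a data frame of saccade
#'   events.
#' @param duration Epoch duration in seconds.
#' @return Saccade count divided by `duration`.
#' @export
saccade_rate <- function(saccades, duration = NULL) {
  sc <- if (inherits(saccades, "cwl_fixations")) saccades$saccades else saccades
  if (is.null(duration) && inherits(saccades, "cwl_fixations")) {
    duration <- saccades$duration
  }
  if (is.null(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  nrow(sc) / duration
}

#' Nearest-neighbour index of spatial dispersion
#'
#' The Clark-Evans-style ratio `NNI = d_nn / d_mrd`, where `d_nn` is the
#' mean nearest-neighbour Euclidean distance among the points and
#' `d_mrd = 0.5 * sqrt(area / N)` is the mean distance expected under
#' complete spatial randomness over the same area. The area is the
#' bounding rectangle of the point coordinates. NNI is about 1 for random
#' scatter, below 1 for clustered points and above 1 for dispersed
#' points; applied to gaze-fixation centroids it indexes how random the
#' visual scan has become, which rises with cognitive load. No edge
#' correction is applied.
#'
#' @param points A `cwl_fixations` object (fixation centroids are used),
#'   or a two-column matrix / data frame of coordinates.
#' @return Object of class `cwl_nni`: list with `d_nn`, `d_mrd`, `nni`,
#'   `n`, `area`. Coincident/collinear points (zero area) give
#'   `nni = 0` with a warning.
#' @export
nni <- function(points) {
  if (inherits(points, "cwl_fixations")) {
    pts <- cbind(points$fixations$fx, points$fixations$fy)
  } else {
    pts <- as.matrix(points)
  }
  if (nrow(pts) < 2) stop("NNI needs at least 2 points", call. = FALSE)
  if (ncol(pts) != 2) stop("points must have exactly 2 coordinates", call. = FALSE)
  n <- nrow(pts)
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  d_nn <- mean(apply(dm, 1, min))
  area <- diff(range(pts[, 1])) * diff(range(pts[, 2]))
  if (area == 0) {
    warning("degenerate point set (zero bounding area); NNI set to 0",
            call. = FALSE)
    return(structure(list(d_nn = d_nn, d_mrd = 0, nni = 0, n = n, area = 0),
                     class = "cwl_nni"))
  }
  d_mrd <- 0.5 * sqrt(area / n)
  structure(list(d_nn = d_nn, d_mrd = d_mrd, nni = d_nn / d_mrd,
                 n = n, area = area),
            class = "cwl_nni")
}

#' @export
print.cwl_nni <- function(x, ...) {
  cat(sprintf("<cwl_nni> NNI = %.4g (d_nn = %.4g, d_mrd = %.4g, n = %d)\n",
              x$nni, x$d_nn, x$d_mrd, x$n))
  invisible(x)
}

#' Detect saccadic intrusions in horizontal gaze
#'
#' A saccadic intrusion (SI) is a small horizontal out-and-back eye
#' movement: the gaze leaves a settled local baseline by more than
#' `min_amplitude`, then returns to within `return_band` of that baseline
#' after 60-870 ms. The baseline is the median of the preceding
#' `baseline_window` seconds, frozen at excursion onset; an excursion can
#' only open while that window is itself stable (range at most
#' `baseline_tol`), so a saccade in flight, whose trailing window still
#' mixes two fixation positions, never seeds a spurious event.
#' Excursions that never return within 870 ms (i.e. genuine saccades to
#' a new fixation target) are not intrusions, and because an intrusion
#' is a *horizontal* movement, excursions accompanied by a vertical
#' displacement beyond `vertical_tol` (refixations that merely happen to
#' land near the old horizontal position) are rejected when a vertical
#' channel is available. The event velocity is the mean out-and-back
#' velocity, `2 * amplitude / duration`.
#'
#' @param horiz A [cwl_ts] containing channel `gaze_x_deg`, or a numeric
#'   vector of horizontal gaze (deg) with `fs` supplied.
#' @param fs Sampling rate (Hz) when `horiz` is a plain vector.
#' @param min_amplitude Minimum excursion amplitude in degrees
#'   (default 0.1).
#' @param max_amplitude Maximum excursion amplitude in degrees
#'   (default 2). Intrusions are small by definition; larger
#'   out-and-back excursions are refixations, not intrusions.
#' @param return_tol Maximum distance (deg) from the pre-excursion
#'   position that still counts as "returned" (default 0.4).
#' @param return_band Deviation (deg) below which the excursion is over;
#'   defaults to `min_amplitude`.
#' @param window Allowed onset-to-return interval in seconds
#'   (default `c(0.06, 0.87)`).
#' @param baseline_window Baseline median window in seconds (default 0.1).
#' @param baseline_tol Maximum range (deg) of the trailing window for the
#'   baseline to count as settled (default `2 * min_amplitude`).
#' @param vertical_tol Maximum vertical displacement (deg) from the
#'   pre-excursion vertical position tolerated during the excursion
#'   (default 0.4); only applied when vertical gaze is available.
#' @return Data frame of class `cwl_si_events` with columns `onset`,
#'   `return`, `duration`, `amplitude` (deg) and `velocity` (deg/s).
#' @export
detect_si <- function(horiz, fs = NULL, min_amplitude = 0.1,
                      max_amplitude = 2,
                      return_tol = 0.4, return_band = min_amplitude,
                      window = c(0.06, 0.87), baseline_window = 0.1,
                      baseline_tol = 2 * min_amplitude, vertical_tol = 0.4) {
  yv <- NULL
  if (inherits(horiz, "cwl_ts")) {
    t <- horiz$t
    x <- horiz$values$gaze_x_deg
    ok <- horiz$valid$gaze_x_deg & is.finite(x)
    if ("gaze_y_deg" %in% names(horiz$values)) yv <- horiz$values$gaze_y_deg
    fs <- horiz$fs
  } else {
    if (is.null(fs)) stop("fs required for a plain numeric trace", call. = FALSE)
    x <- as.numeric(horiz)
    t <- (seq_along(x) - 1) / fs
    ok <- is.finite(x)
  }
  empty <- data.frame(onset = numeric(), `return` = numeric(),
                      duration = numeric(), amplitude = numeric(),
                      velocity = numeric())
  class(empty) <- c("cwl_si_events", "data.frame")
  n <- length(x)
  if (n < 2 || diff(range(t)) < window[2]) {
    warning("epoch shorter than the maximum SI return window; no detection",
            call. = FALSE)
    return(empty)
  }
  k <- max(3L, round(baseline_window * fs))
  # trailing-window stability (range over the k samples before i) and
  # baseline (mean of that window); both lagged so sample i is excluded
  xr <- x; xr[!ok] <- NA
  rmax <- rmin <- rsum <- rok <- rep(NA_real_, n)
  shift <- function(v, s) c(rep(NA_real_, s), v[seq_len(n - s)])
  mx <- mn <- sm <- cnt <- NULL
  for (s in seq_len(k)) {
    xs <- shift(xr, s)
    if (s == 1L) {
      mx <- xs; mn <- xs; sm <- ifelse(is.na(xs), 0, xs)
      cnt <- as.numeric(!is.na(xs))
    } else {
      mx <- pmax(mx, xs, na.rm = TRUE)
      mn <- pmin(mn, xs, na.rm = TRUE)
      sm <- sm + ifelse(is.na(xs), 0, xs)
      cnt <- cnt + !is.na(xs)
    }
  }
  stable <- cnt == k & (mx - mn) <= baseline_tol
  stable[is.na(stable)] <- FALSE
  baseline <- sm / pmax(cnt, 1)
  max_look <- ceiling(window[2] * fs) + 1L
  events <- list()
  i <- k + 1L
  while (i <= n) {
    if (!ok[i] || !stable[i] || abs(x[i] - baseline[i]) <= min_amplitude) {
      i <- i + 1L; next
    }
    b0 <- stats::median(x[(i - k):(i - 1L)])
    if (abs(x[i] - b0) <= min_amplitude) { i <- i + 1L; next }
    j_end <- min(n, i + max_look)
    seg <- i:j_end
    dev <- abs(x[seg] - b0)
    dev[!ok[seg]] <- Inf
    back <- which(dev <= return_band)
    if (length(back)) {
      j <- seg[back[1]]
      dur <- t[j] - t[i]
      amp <- max(dev[1:back[1]][is.finite(dev[1:back[1]])])
      vert_ok <- TRUE
      if (!is.null(yv)) {
        y0 <- stats::median(yv[(i - k):(i - 1L)], na.rm = TRUE)
        ydev <- abs(yv[seg[1:back[1]]] - y0)
        vert_ok <- all(is.na(ydev) | ydev <= vertical_tol)
      }
      if (dur >= window[1] && dur <= window[2] &&
          amp <= max_amplitude && abs(x[j] - b0) <= return_tol && vert_ok) {
        events[[length(events) + 1L]] <- data.frame(
          onset = t[i], `return` = t[j], duration = dur,
          amplitude = amp, velocity = 2 * amp / dur)
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  class(out) <- c("cwl_si_events", "data.frame")
  out
}

#' Median saccadic-intrusion velocity
#'
#' @param events SI events from [detect_si].
#' @return Median of the event velocities in deg/s; `NA` when there are
#'   no events.
#' @export
median_si_velocity <- function(events) {
  if (is.null(events) || !nrow(events)) return(NA_real_)
  stats::median(events$velocity)
}
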
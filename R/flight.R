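#' Construct an inceptor deflection trace
#'
#' @param t Timestamps in seconds, strictly increasing.
#' @param defl Inceptor deflection in mm.
#' @param delta_max Full-scale stick deflection in mm (default 100).
#' @param noise_threshold Deflection-rate noise floor in mm/s below which
#'   the stick is considered idle (default 0.5).
#' @return Object of class `inceptor_trace`.
#' @export
inceptor_trace <- function(t, defl, delta_max = 100, noise_threshold = 0.5) {
  stopifnot(length(t) == length(defl), noise_threshold > 0, delta_max > 0)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("inceptor timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(abs(defl) > delta_max + 1e-9)) {
    stop("deflection exceeds delta_max", call. = FALSE)
  }
  structure(list(t = as.numeric(t), defl = as.numeric(defl),
                 delta_max = delta_max, noise_threshold = noise_threshold),
            class = "inceptor_trace")
}

#' Inceptor duty cycle
#'
#' The percentage of time the pilot is actively moving the inceptor. An
#' inter-sample interval is active (`x_i = 1`) when the absolute
#' deflection rate `|delta_i - delta_{i-1}| / (t_i - t_{i-1})` reaches the
#' noise threshold, or the stick is pinned at full deflection; otherwise
#' idle (`x_i = 0`).
#'
#' Two aggregation modes:
#' * `"time_weighted"` (default): `DC = 100 * sum(x_i * dt_i) / (t_n - t_1)`,
#'   a true percentage of elapsed time, bounded by 100 for any sampling.
#' * `"per_sample"`: `DC = 100 * sum(x_i) / (t_n - t_2)`, the raw
#'   per-sample count over elapsed time; equal to the time-weighted value
#'   up to the `(n-1)/(n-2)` edge factor under uniform sampling, but not a
#'   bounded percentage for irregular sampling. Kept for comparison.
#'
#' @param trace An `inceptor_trace` with at least 3 samples.
#' @param method Aggregation mode, see above.
#' @return Duty cycle in percent.
#' @export
duty_cycle <- function(trace, method = c("time_weighted", "per_sample")) {
  stopifnot(inherits(trace, "inceptor_trace"))
  method <- match.arg(method)
  n <- length(trace$t)
  if (n < 3) stop("duty cycle needs at least 3 samples", call. = FALSE)
  dt <- diff(trace$t)
  rate <- abs(diff(trace$defl)) / dt
  x <- as.numeric(!(rate < trace$noise_threshold &
                      abs(trace$defl[-1]) < trace$delta_max))
  if (method == "time_weighted") {
    100 * sum(x * dt) / (trace$t[n] - trace$t[1])
  } else {
    100 * sum(x) / (trace$t[n] - trace$t[2])
  }
}

#' Inceptor aggressiveness
#'
#' Mean squared deflection rate,
#' `(1/(n-1)) * sum(((delta_i - delta_{i-1}) / (t_i - t_{i-1}))^2)`:
#' how abruptly the pilot works the stick, independent of where the stick
#' sits (adding a constant offset changes nothing).
#'
#' @param trace An `inceptor_trace` with at least 2 samples.
#' @return Aggressiveness in (mm/s)^2.
#' @export
aggressiveness <- function(trace) {
  stopifnot(inherits(trace, "inceptor_trace"))
  if (length(trace$t) < 2) stop("aggressiveness needs at least 2 samples",
                                call. = FALSE)
  rates <- diff(trace$defl) / diff(trace$t)
  mean(rates^2)
}

#' Percentage RMSE of a flight-state channel against its reference
#'
#' Root-mean-square deviation of the flown value from the target,
#' expressed as a percentage of the target. For the altitude task the
#' target is the midpoint of the assigned altitude band; for airspeed it
#' is the trim airspeed.
#'
#' @param trace A flight [cwl_ts] (channels `altitude_ft`,
#'   `airspeed_kt`).
#' @param channel `"altitude"` or `"airspeed"`.
#' @param alt_band Assigned altitude band in ft (default
#'   `c(4000, 5000)`; target = midpoint).
#' @param airspeed_target Trim airspeed in knots (default 120).
#' @return `100 * RMSE / target`, in percent.
#' @export
rmse_percent <- function(trace, channel = c("altitude", "airspeed"),
                         alt_band = c(4000, 5000), airspeed_target = 120) {
  stopifnot(inherits(trace, "cwl_ts"))
  channel <- match.arg(channel)
  if (channel == "altitude") {
    stopifnot(alt_band[1] < alt_band[2])
    target <- mean(alt_band)
    v <- ts_channel(trace, "altitude_ft", valid_only = TRUE)$value
  } else {
    target <- airspeed_target
    v <- ts_channel(trace, "airspeed_kt", valid_only = TRUE)$value
  }
  if (!length(v)) stop("empty flight trace", call. = FALSE)
  if (target <= 0) stop("reference target must be positive", call. = FALSE)
  100 * sqrt(mean((v - target)^2)) / target
}

#' Pilot-inceptor-workload (PIW) point
#'
#' The (aggressiveness, duty cycle) pair for one recording; the scatter
#' of these points across conditions is the PIW plot used to read off
#' control workload.
#'
#' @param trace An `inceptor_trace`.
#' @param ... Passed to [duty_cycle].
#' @return Data frame with `aggressiveness` ((mm/s)^2) and `duty_cycle`
#'   (percent).
#' @export
piw_point <- function(trace, ...) {
  data.frame(aggressiveness = aggressiveness(trace),
             duty_cycle = duty_cycle(trace, ...))
}
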
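# CSV recording schemas. One file per modality, timestamps in seconds in
# column `t_s`. These are the only on-disk formats the pipeline reads; the
# synthetic generator writes the identical dialect so synthetic and real
# studies take the same code path.
.cwl_schemas <- list(
  gaze     = c("t_s", "gaze_x_deg", "gaze_y_deg", "pupil_left_mm",
               "pupil_right_mm", "valid_left", "valid_right"),
  eeg      = c("t_s", "AF3_uV", "AF4_uV", "T7_uV", "T8_uV", "Pz_uV"),
  inceptor = c("t_s", "defl_mm"),
  flight   = c("t_s", "altitude_ft", "airspeed_kt"),
  events   = c("t_s", "kind", "label")
)

.cwl_units <- list(
  gaze     = c(gaze_x_deg = "deg", gaze_y_deg = "deg",
               pupil_left_mm = "mm", pupil_right_mm = "mm"),
  eeg      = c(AF3_uV = "uV", AF4_uV = "uV", T7_uV = "uV",
               T8_uV = "uV", Pz_uV = "uV"),
  inceptor = c(defl_mm = "mm"),
  flight   = c(altitude_ft = "ft", airspeed_kt = "kt"),
  events   = character()
)

#' Read a recording CSV
#'
#' Reads and validates one of the five recording schemas. Invalid samples
#' (non-finite values, or gaze samples with the eye-tracker validity flag
#' down) are flagged, not dropped, so later stages decide how to treat them.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"gaze"`, `"eeg"`, `"inceptor"`, `"flight"`,
#'   `"events"`.
#' @param fs_nominal Optional declared sampling rate (Hz). A warning is
#'   raised if it disagrees with the median sample interval by more than
#'   10 percent. Ignored for `"events"`.
#' @return A [cwl_ts] for signal schemas; a data frame of class
#'   `cwl_events` (columns `t`, `kind`, `label`) for `"events"`.
#' @export
read_recording <- function(path, schema = c("gaze", "eeg", "inceptor",
                                            "flight", "events"),
                           fs_nominal = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- .cwl_schemas[[schema]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema '%s': missing column(s): %s", schema,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  t <- as.numeric(df$t_s)
  if (schema == "events") {
    if (is.unsorted(t)) {
      stop(sprintf("events: timestamps not nondecreasing at row %d",
                   which(diff(t) < 0)[1] + 1L), call. = FALSE)
    }
    ev <- data.frame(t = t, kind = as.character(df$kind),
                     label = as.character(df$label), stringsAsFactors = FALSE)
    bad_kind <- setdiff(unique(ev$kind),
                        c("stimulus", "response", "segment_start", "segment_end"))
    if (length(bad_kind)) {
      stop(sprintf("events: unknown kind(s): %s", paste(bad_kind, collapse = ", ")),
           call. = FALSE)
    }
    ns <- sum(ev$kind == "segment_start")
    ne <- sum(ev$kind == "segment_end")
    if (ns != ne) {
      stop(sprintf("events: %d segment_start vs %d segment_end rows", ns, ne),
           call. = FALSE)
    }
    class(ev) <- c("cwl_events", "data.frame")
    return(ev)
  }
  if (anyDuplicated(t) || is.unsorted(t, strictly = TRUE)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    stop(sprintf("schema '%s': timestamps not strictly increasing at row %d",
                 schema, bad), call. = FALSE)
  }
  chans <- setdiff(need, c("t_s", "valid_left", "valid_right"))
  values <- df[chans]
  values[] <- lapply(values, as.numeric)
  valid <- as.data.frame(lapply(values, is.finite))
  if (schema == "gaze") {
    vl <- as.logical(df$valid_left)
    vr <- as.logical(df$valid_right)
    vl[is.na(vl)] <- FALSE
    vr[is.na(vr)] <- FALSE
    valid$pupil_left_mm <- valid$pupil_left_mm & vl
    valid$pupil_right_mm <- valid$pupil_right_mm & vr
    # gaze direction needs at least one tracked eye
    valid$gaze_x_deg <- valid$gaze_x_deg & (vl | vr)
    valid$gaze_y_deg <- valid$gaze_y_deg & (vl | vr)
  }
  out <- cwl_ts(t, values, valid, units = .cwl_units[[schema]])
  if (!is.null(fs_nominal) && length(t) > 1) {
    fs_obs <- 1 / stats::median(diff(t))
    if (abs(fs_obs - fs_nominal) > 0.1 * fs_nominal) {
      warning(sprintf(
        "declared rate %.4g Hz differs from observed %.4g Hz by more than 10%%",
        fs_nominal, fs_obs), call. = FALSE)
    }
    out$fs <- fs_nominal
  }
  out
}

#' Write a recording CSV
#'
#' Inverse of [read_recording]; used by the synthetic study generator so
#' the pipeline never special-cases synthetic input.
#'
#' @param x A [cwl_ts] (signal schemas) or `cwl_events` data frame.
#' @param path Output CSV path.
#' @param schema Schema name, as in [read_recording].
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path, schema = c("gaze", "eeg", "inceptor",
                                                "flight", "events")) {
  schema <- match.arg(schema)
  if (schema == "events") {
    df <- data.frame(t_s = x$t, kind = x$kind, label = x$label)
  } else {
    stopifnot(inherits(x, "cwl_ts"))
    df <- cbind(data.frame(t_s = x$t), x$values)
    if (schema == "gaze") {
      df$valid_left <- x$valid$pupil_left_mm
      df$valid_right <- x$valid$pupil_right_mm
    }
    df <- df[.cwl_schemas[[schema]]]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Cut a recording into event-delimited segments
#'
#' Segments are defined by matching `segment_start` / `segment_end` pairs
#' (paired in file order) whose `label` equals `label`. Each returned
#' segment spans the closed interval `[start, end]`; samples outside all
#' segments are discarded.
#'
#' @param series A [cwl_ts].
#' @param log A `cwl_events` data frame from [read_recording].
#' @param label Segment label to extract.
#' @return List of [cwl_ts] segments, in log order. A warning (and an
#'   empty list) results when no segment carries the label.
#' @export
segment_by_events <- function(series, log, label) {
  stopifnot(inherits(series, "cwl_ts"))
  starts <- log$t[log$kind == "segment_start" & log$label == label]
  ends <- log$t[log$kind == "segment_end" & log$label == label]
  if (!length(starts)) {
    warning(sprintf("no segment with label '%s'", label), call. = FALSE)
    return(list())
  }
  if (length(starts) != length(ends)) {
    stop(sprintf("label '%s': %d segment_start but %d segment_end events",
                 label, length(starts), length(ends)), call. = FALSE)
  }
  lapply(seq_along(starts), function(i) {
    s <- starts[i]; e <- ends[i]
    if (e > max(series$t)) {
      warning(sprintf("segment [%g, %g] extends beyond recording end %g; truncated",
                      s, e, max(series$t)), call. = FALSE)
    }
    keep <- series$t >= s & series$t <= e
    cwl_ts(series$t[keep], series$values[keep, , drop = FALSE],
           series$valid[keep, , drop = FALSE], fs = series$fs,
           units = series$units)
  })
}

#' Outer-fence outlier filter
#'
#' Removes values outside the outer Tukey fences
#' `[Q1 - k * IQR, Q3 + k * IQR]` with `k = 3` (the "outer" fence; the
#' familiar boxplot whisker uses 1.5). Quartiles are computed by linear
#' interpolation of the empirical CDF (`quantile` type 7); the convention
#' is configurable.
#'
#' @param x Numeric vector with at least 4 finite values.
#' @param k Fence multiplier (default 3, the outer fence).
#' @param qtype Quantile algorithm passed to [stats::quantile()].
#' @return List with `kept` (values inside the fences, order preserved)
#'   and `removed_mask` (logical, `TRUE` where a value was removed; `TRUE`
#'   also for non-finite values).
#' @export
outer_fence_filter <- function(x, k = 3, qtype = 7) {
  fin <- is.finite(x)
  if (sum(fin) < 4) {
    stop("outer_fence_filter needs at least 4 finite values", call. = FALSE)
  }
  q <- stats::quantile(x[fin], c(0.25, 0.75), type = qtype, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  removed <- !fin | x < lo | x > hi
  list(kept = x[!removed], removed_mask = removed,
       fences = c(lower = lo, upper = hi))
}
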
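# Orchestration: per-recording metric extraction -> outer fencing ->
# normality gate -> omnibus + pairwise tests per metric -> Spearman
# conformance matrix. Operates identically on on-disk studies (CSV
# layout written by gen_study) and in-memory cwl_study objects.

.metric_names <- c("l1ns_left", "l1ns_right", "stdp_left", "stdp_right",
                   "lpf_left", "lpf_right",
                   "nni", "fixation_rate", "saccade_rate",
                   "median_si_velocity",
                   "power_theta", "power_alpha", "power_lb", "power_hb",
                   "duty_cycle", "aggressiveness",
                   "rmse_altitude_pct", "rmse_airspeed_pct")

# metrics from one recording set; failures in one modality only lose
# that modality's metrics
.metrics_one <- function(rec, id = "") {
  nm <- character(); val <- numeric()
  add <- function(metric, value) {
    nm <<- c(nm, metric); val <<- c(val, as.numeric(value))
  }
  try_modality <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      warning(sprintf("%s: %s metrics failed: %s", id, what,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  }
  try_modality("pupil", {
    for (eye in c("left", "right")) {
      ep <- pupil_from_gaze(rec$gaze, eye)
      pieces <- preprocess_pupil(ep)
      lens <- vapply(pieces, function(p) length(p$t), numeric(1))
      best <- pieces[[which.max(lens)]]
      add(paste0("l1ns_", eye), l1ns(best))
      add(paste0("stdp_", eye), stdp(best))
      add(paste0("lpf_", eye), lpf_metric(best))
    }
  })
  try_modality("gaze", {
    fx <- ivt_classify(rec$gaze)
    if (fx$n >= 2) add("nni", nni(fx)$nni)
    add("fixation_rate", fixation_rate(fx))
    add("saccade_rate", saccade_rate(fx))
    si <- detect_si(rec$gaze)
    add("median_si_velocity", median_si_velocity(si))
  })
  try_modality("eeg", {
    bp <- band_power_summary(rec$eeg)$median
    add("power_theta", bp$power[bp$band == "theta"])
    add("power_alpha", bp$power[bp$band == "alpha"])
    add("power_lb", bp$power[bp$band == "low_beta"])
    add("power_hb", bp$power[bp$band == "high_beta"])
  })
  try_modality("flight", {
    add("duty_cycle", duty_cycle(rec$inceptor))
    add("aggressiveness", aggressiveness(rec$inceptor))
    add("rmse_altitude_pct", rmse_percent(rec$flight, "altitude"))
    add("rmse_airspeed_pct", rmse_percent(rec$flight, "airspeed"))
  })
  if (!length(nm)) return(NULL)
  data.frame(metric = nm, value = val)
}

# load one on-disk recording set; an unreadable modality becomes NULL
# (with a warning) so the other modalities still yield metrics
.read_recording_set <- function(dir) {
  grab <- function(file, schema, post = identity) {
    tryCatch(post(read_recording(file.path(dir, file), schema)),
             error = function(e) {
               warning(sprintf("%s: %s", file.path(dir, file),
                               conditionMessage(e)), call. = FALSE)
               NULL
             })
  }
  list(gaze = grab("gaze.csv", "gaze"),
       eeg = grab("eeg.csv", "eeg"),
       inceptor = grab("inceptor.csv", "inceptor",
                       function(ts) inceptor_trace(ts$t, ts$values$defl_mm)),
       flight = grab("flight.csv", "flight"),
       events = grab("events.csv", "events"))
}

#' Extract the metric table of a study
#'
#' Runs every metric on every participant-condition recording set and
#' returns the long-form bridge table between the signal level and the
#' statistics level. A failure in one recording's modality drops only
#' that cell's metrics (with a warning); the rest of the table is kept.
#'
#' @param study A `cwl_study` (from [gen_study()]) or the path of a
#'   study directory laid out as `P../C../{gaze,eeg,inceptor,flight,events}.csv`.
#' @return Data frame with columns `participant`, `condition`, `metric`,
#'   `value`.
#' @export
extract_metrics <- function(study) {
  sets <- list()
  if (inherits(study, "cwl_study") && !is.null(study$recordings)) {
    for (key in names(study$recordings)) {
      pc <- strsplit(key, ">", fixed = TRUE)[[1]]
      sets[[key]] <- list(participant = pc[1], condition = pc[2],
                          rec = study$recordings[[key]])
    }
  } else {
    dir <- if (inherits(study, "cwl_study")) study$dir else study
    if (is.null(dir) || !dir.exists(dir)) {
      stop("study directory not found", call. = FALSE)
    }
    pdirs <- list.dirs(dir, recursive = FALSE)
    pdirs <- pdirs[grepl("^P", basename(pdirs))]
    if (!length(pdirs)) stop("no participant directories found", call. = FALSE)
    for (pd in pdirs) {
      for (cd in list.dirs(pd, recursive = FALSE)) {
        key <- paste0(basename(pd), ">", basename(cd))
        sets[[key]] <- list(participant = basename(pd),
                            condition = basename(cd), rec = NULL, dir = cd)
      }
    }
  }
  rows <- list()
  for (key in names(sets)) {
    s <- sets[[key]]
    rec <- s$rec
    if (is.null(rec)) {
      rec <- tryCatch(.read_recording_set(s$dir), error = function(e) {
        warning(sprintf("%s: unreadable recording set: %s", key,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(rec)) next
    }
    m <- .metrics_one(rec, key)
    if (is.null(m)) next
    m$participant <- s$participant
    m$condition <- s$condition
    rows[[key]] <- m[c("participant", "condition", "metric", "value")]
  }
  if (!length(rows)) stop("no metrics could be extracted", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# wide participants x conditions matrix for one metric
.metric_matrix <- function(table, metric) {
  sub <- table[table$metric == metric, ]
  if (!nrow(sub)) return(NULL)
  parts <- sort(unique(sub$participant))
  conds <- unique(table$condition)
  m <- matrix(NA_real_, length(parts), length(conds),
              dimnames = list(parts, conds))
  for (i in seq_len(nrow(sub))) {
    m[sub$participant[i], sub$condition[i]] <- sub$value[i]
  }
  m
}

.sig_flag <- function(p, alpha_levels = c(0.1, 0.05, 0.01)) {
  a <- sort(alpha_levels)
  if (is.na(p)) return("")
  if (p < a[1]) "**" else if (p < a[2]) "*" else if (p < a[3]) "." else ""
}

#' Compare task conditions metric by metric
#'
#' The repeated-measures comparison harness: per metric, outer-fence
#' outlier removal (within condition, across participants), an
#' Anderson-Darling normality gate on the condition-centred values, the
#' matching omnibus test (Friedman when non-normal, one-way
#' repeated-measures ANOVA when normal) and all pairwise Wilcoxon
#' signed-rank tests, flagged at the configured significance levels.
#'
#' @param table Metric table from [extract_metrics()].
#' @param gate `"auto"` (Anderson-Darling decides per metric),
#'   `"nonparametric"` or `"parametric"`.
#' @param gate_alpha Significance level of the normality gate.
#' @param fence Apply outer fencing before testing?
#' @param fence_k Outer-fence multiplier.
#' @param alpha_levels Flag thresholds, most to least stringent
#'   (default 0.1 / 0.05 / 0.01, flagged `.`, `*`, `**`).
#' @param min_pairs Minimum complete participants required to test a
#'   metric (default 5); below it the metric is skipped with its reason
#'   recorded.
#' @return List of class `cwl_comparison`: `omnibus` (one row per
#'   metric), `pairwise` (one row per metric x condition pair),
#'   `skipped`, and the settings used.
#' @export
compare_conditions <- function(table, gate = c("auto", "nonparametric",
                                               "parametric"),
                               gate_alpha = 0.05, fence = TRUE, fence_k = 3,
                               alpha_levels = c(0.1, 0.05, 0.01),
                               min_pairs = 5) {
  gate <- match.arg(gate)
  metrics <- unique(table$metric)
  conds <- unique(table$condition)
  omni <- list(); pairwise <- list(); skipped <- list()
  if (length(conds) < 2) {
    return(structure(list(
      omnibus = data.frame(), pairwise = data.frame(),
      skipped = data.frame(metric = metrics,
                           reason = "fewer than 2 conditions"),
      gate = gate, alpha_levels = alpha_levels),
      class = "cwl_comparison"))
  }
  for (met in metrics) {
    m <- .metric_matrix(table, met)
    if (is.null(m)) next
    if (fence) {
      for (j in seq_len(ncol(m))) {
        v <- m[, j]
        if (sum(is.finite(v)) >= 4) {
          f <- outer_fence_filter(v, k = fence_k)
          m[f$removed_mask, j] <- NA
        }
      }
    }
    complete <- stats::complete.cases(m)
    mc <- m[complete, , drop = FALSE]
    if (nrow(mc) < min_pairs) {
      skipped[[met]] <- data.frame(metric = met, reason = sprintf(
        "only %d complete participants (need >= %d)", nrow(mc), min_pairs))
      next
    }
    centred <- as.vector(scale(mc, center = TRUE, scale = FALSE))
    use_np <- switch(gate,
      nonparametric = TRUE,
      parametric = FALSE,
      auto = tryCatch(
        anderson_darling_normal(centred)$p_value < gate_alpha,
        error = function(e) TRUE))
    rep <- if (use_np) friedman_test(mc) else rm_anova_oneway(mc)
    omni[[met]] <- data.frame(
      metric = met, test = rep$test,
      statistic = unname(rep$statistic[1]),
      df = paste(rep$df, collapse = ","),
      p_value = rep$p_value, n = nrow(mc),
      flag = .sig_flag(rep$p_value, alpha_levels))
    cmb <- utils::combn(conds, 2)
    for (q in seq_len(ncol(cmb))) {
      c1 <- cmb[1, q]; c2 <- cmb[2, q]
      ok <- is.finite(m[, c1]) & is.finite(m[, c2])
      pr <- tryCatch(wilcoxon_signed_rank(m[ok, c1], m[ok, c2]),
                     error = function(e) NULL)
      pairwise[[paste(met, c1, c2)]] <- data.frame(
        metric = met, pair = paste0(c1, "-", c2),
        W = if (is.null(pr)) NA_real_ else unname(pr$statistic["W"]),
        Z = if (is.null(pr)) NA_real_ else unname(pr$statistic["Z"]),
        p_value = if (is.null(pr)) NA_real_ else pr$p_value,
        n = sum(ok),
        flag = .sig_flag(if (is.null(pr)) NA_real_ else pr$p_value,
                         alpha_levels))
    }
  }
  structure(list(
    omnibus = if (length(omni)) do.call(rbind, c(omni, make.row.names = FALSE))
      else data.frame(),
    pairwise = if (length(pairwise))
      do.call(rbind, c(pairwise, make.row.names = FALSE)) else data.frame(),
    skipped = if (length(skipped))
      do.call(rbind, c(skipped, make.row.names = FALSE)) else
        data.frame(metric = character(), reason = character()),
    gate = gate, alpha_levels = alpha_levels),
    class = "cwl_comparison")
}

#' @export
print.cwl_comparison <- function(x, ...) {
  cat(sprintf("<cwl_comparison> %d metric(s), gate = %s\n",
              nrow(x$omnibus), x$gate))
  if (nrow(x$omnibus)) print(x$omnibus, row.names = FALSE)
  invisible(x)
}

#' Default conformance metric pairs
#'
#' The cross-modality pairs examined for agreement among workload
#' indicators: low-beta vs theta power, low-beta vs high-beta power,
#' NNI vs L1NS, L1NS vs low-beta power, duty cycle vs L1NS, duty cycle
#' vs theta power.
#'
#' @return List of length-2 character vectors.
#' @export
conformance_pairs <- function() {
  list(c("power_lb", "power_theta"),
       c("power_lb", "power_hb"),
       c("nni", "l1ns_left"),
       c("l1ns_left", "power_lb"),
       c("duty_cycle", "l1ns_left"),
       c("duty_cycle", "power_theta"))
}

#' Conformance (rank-correlation) analysis between metrics
#'
#' Spearman rank correlation between metric pairs, pooling all
#' participant x condition values (one point per recording). This is
#' the "do independent workload indicators agree" analysis; a shared
#' latent workload driving two metrics shows up as a positive rho.
#'
#' @param table Metric table from [extract_metrics()].
#' @param pairs List of metric-name pairs (default [conformance_pairs()]).
#' @param min_n Minimum paired observations per pair (default 10);
#'   sparser pairs are reported with `NA`.
#' @return Data frame of class `cwl_conformance`: `metric_a`,
#'   `metric_b`, `n`, `rho`, `p_value`.
#' @export
conformance <- function(table, pairs = conformance_pairs(), min_n = 10) {
  rows <- list()
  for (pr in pairs) {
    a <- table[table$metric == pr[1], c("participant", "condition", "value")]
    b <- table[table$metric == pr[2], c("participant", "condition", "value")]
    mg <- merge(a, b, by = c("participant", "condition"),
                suffixes = c("_a", "_b"))
    mg <- mg[is.finite(mg$value_a) & is.finite(mg$value_b), ]
    if (nrow(mg) < min_n) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric_a = pr[1], metric_b = pr[2], n = nrow(mg),
        rho = NA_real_, p_value = NA_real_)
      next
    }
    sp <- spearman_rho(mg$value_a, mg$value_b)
    rows[[length(rows) + 1L]] <- data.frame(
      metric_a = pr[1], metric_b = pr[2], n = sp$n,
      rho = unname(sp$statistic["rho"]), p_value = sp$p_value)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cwl_conformance", "data.frame")
  out
}

#' Full Spearman correlation matrix over metrics
#'
#' @param table Metric table from [extract_metrics()].
#' @param metrics Metric names to include (default: all in the table).
#' @return List with `rho` and `p` matrices; `rho` is symmetric with a
#'   unit diagonal.
#' @export
conformance_matrix <- function(table, metrics = unique(table$metric)) {
  k <- length(metrics)
  rho <- diag(1, k); p <- diag(0, k)
  dimnames(rho) <- dimnames(p) <- list(metrics, metrics)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- table[table$metric == metrics[i], c("participant", "condition", "value")]
      b <- table[table$metric == metrics[j], c("participant", "condition", "value")]
      mg <- merge(a, b, by = c("participant", "condition"),
                  suffixes = c("_a", "_b"))
      mg <- mg[is.finite(mg$value_a) & is.finite(mg$value_b), ]
      sp <- tryCatch(spearman_rho(mg$value_a, mg$value_b),
                     error = function(e) NULL)
      rho[i, j] <- rho[j, i] <- if (is.null(sp)) NA_real_ else
        unname(sp$statistic["rho"])
      p[i, j] <- p[j, i] <- if (is.null(sp)) NA_real_ else sp$p_value
    }
  }
  list(rho = rho, p = p)
}

#' Run the complete analysis on a study
#'
#' Metric extraction, condition comparison and conformance analysis in
#' one call: the full workload-estimation analysis from raw recordings
#' to the comparison and correlation tables.
#'
#' @param study A `cwl_study` or study directory path.
#' @param ... Passed to [compare_conditions()].
#' @param pairs Conformance pairs (default [conformance_pairs()]).
#' @return List of class `cwl_report`: `metrics`, `comparison`,
#'   `conformance`, `provenance`.
#' @export
analyze_study <- function(study, ..., pairs = conformance_pairs()) {
  mt <- extract_metrics(study)
  cmp <- compare_conditions(mt, ...)
  conf <- conformance(mt, pairs)
  structure(list(metrics = mt, comparison = cmp, conformance = conf,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("cogload")),
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "cwl_report")
}

#' Write an analysis report to JSON
#'
#' @param report A `cwl_report` from [analyze_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(omnibus = report$comparison$omnibus,
         pairwise = report$comparison$pairwise,
         skipped = report$comparison$skipped,
         conformance = as.data.frame(report$conformance),
         provenance = report$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
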
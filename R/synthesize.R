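# Synthetic multi-condition study generator.
#
# Signal models are intentionally minimal (sinusoid banks, bout processes,
# AR(1) errors plus noise): each workload-sensitive property that a metric
# measures -- 1-5 Hz pupil-spectrum amplitude, fixation-cluster spread, EEG
# band amplitudes, inceptor activity fraction, tracking-error SD, saccadic-
# intrusion rate -- is independently tunable through an effect map, so every
# stage of the pipeline can be checked against known ground truth.
# Physiological realism (pupil light reflex, EEG nonstationarity, coupled
# flight dynamics) is explicitly not a goal.

# evaluate expr under a fully specified, restorable RNG state
.with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# deterministic sub-stream seed, kept below 2^31 - 1
.derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647
  s <- seed %% m
  for (k in idx) s <- (s * 48271 + k * 10007 + 1) %% m
  as.integer(s)
}

#' Default workload effect map
#'
#' Multiplicative gains applied as `(1 + gain * workload)` to each
#' workload-sensitive signal property. Defaults follow the study design
#' this generator emulates: strong effects on the 1-5 Hz pupil component,
#' fixation dispersion, theta / low-beta EEG power and inceptor activity;
#' moderate effects on alpha / high-beta and tracking error; and no
#' effect on the saccadic-intrusion rate or the fixation-duration share,
#' whose observed insensitivity to load is part of the pattern being
#' reproduced.
#'
#' @return Named list of gains.
#' @export
default_gains <- function() {
  list(pupil_band = 2,
       dispersion = 2.5,
       eeg = c(theta = 1.2, alpha = 0.8, low_beta = 1.2, high_beta = 1.0),
       inceptor = 0.5,
       tracking_error = 1.5,
       si_rate = 0,
       fixation_share = 0)
}

#' Generate a synthetic pupil-diameter epoch pair
#'
#' Baseline diameter + slow drift (below 0.2 Hz, standing in for ambient
#' luminance response) + a band-limited 1-5 Hz component whose total
#' amplitude is `band_amp * (1 + band_gain * workload)` + white noise.
#' Left and right eyes share the drift and band component (correlation
#' about 0.9 at the default noise level) and differ in independent noise
#' and a small baseline offset. Optional blink gaps flag samples invalid.
#'
#' @param workload Scalar workload level in `[0, 1]`.
#' @param duration Epoch length in seconds.
#' @param fs Sampling rate in Hz (>= 20).
#' @param seed RNG seed.
#' @param baseline Mean diameter, mm.
#' @param drift_amp,drift_freq Slow drift amplitude (mm) and frequency
#'   (Hz, < 0.2).
#' @param band_amp Base total amplitude of the 1-5 Hz component, mm.
#' @param band_gain Workload gain on the band amplitude.
#' @param noise_sd Per-eye white-noise SD, mm.
#' @param n_components Number of sinusoids making up the band component.
#' @param blink_rate Blinks per minute (0 disables blink gaps).
#' @return List with `left` and `right` [pupil_epoch]s; attribute
#'   `truth` records the realised band amplitude.
#' @export
gen_pupil <- function(workload, duration = 60, fs = 100, seed = 1,
                      baseline = 3, drift_amp = 0.1, drift_freq = 0.05,
                      band_amp = 0.05, band_gain = 2, noise_sd = 0.01,
                      n_components = 8, blink_rate = 0) {
  stopifnot(fs >= 20)
  .with_seed(seed, {
    n <- round(duration * fs)
    t <- (seq_len(n) - 1) / fs
    amp_tot <- band_amp * (1 + band_gain * workload)
    freqs <- stats::runif(n_components, 1.2, 4.8)
    phases <- stats::runif(n_components, 0, 2 * pi)
    band <- rowSums(vapply(seq_len(n_components), function(i) {
      (amp_tot / n_components) * sin(2 * pi * freqs[i] * t + phases[i])
    }, numeric(n)))
    drift <- drift_amp * sin(2 * pi * drift_freq * t + stats::runif(1, 0, 2 * pi))
    shared <- drift + band
    left <- baseline + shared + stats::rnorm(n, 0, noise_sd)
    right <- baseline - 0.05 + shared + stats::rnorm(n, 0, noise_sd)
    valid_l <- rep(TRUE, n); valid_r <- rep(TRUE, n)
    if (blink_rate > 0) {
      n_blinks <- stats::rpois(1, blink_rate * duration / 60)
      if (n_blinks > 0) {
        onsets <- stats::runif(n_blinks, 0, duration - 0.4)
        durs <- stats::runif(n_blinks, 0.1, 0.3)
        for (b in seq_len(n_blinks)) {
          gap <- t >= onsets[b] & t <= onsets[b] + durs[b]
          valid_l[gap] <- FALSE; valid_r[gap] <- FALSE
        }
      }
    }
    out <- list(left = pupil_epoch(t, left, "left", fs, valid_l),
                right = pupil_epoch(t, right, "right", fs, valid_r))
    attr(out, "truth") <- list(band_amplitude = amp_tot, workload = workload)
    out
  })
}

# fixed instrument-like cluster layout (deg): out-of-window view, primary
# flight display, nav display, secondary display
.gaze_centers <- matrix(c(0, 5, -6, -3, 6, -3, 0, -6), ncol = 2, byrow = TRUE)

#' Generate a synthetic gaze recording
#'
#' Fixation targets are drawn around `n_clusters` fixed instrument-like
#' cluster centres; the cluster spread grows as
#' `base_spread * (1 + dispersion_gain * workload)` and the probability
#' of jumping to another cluster grows with workload, so the scanpath
#' moves from tight, repetitive scanning toward spatially random
#' scanning as load rises. Dwell times are uniform on `dwell` seconds;
#' transitions are instantaneous sample-to-sample jumps, and successive
#' targets are kept at least `min_jump` degrees apart, so every
#' transition registers as a suprathreshold saccade of the same sample
#' cost at every workload level and the fixation-time share depends only
#' on the dwell distribution. Saccadic intrusions obeying the
#' 60-870 ms out-and-back definition are planted inside long fixations
#' at `si_rate * (1 + si_rate_gain * workload)` events per second.
#'
#' @param workload Scalar workload in `[0, 1]`.
#' @param duration Seconds.
#' @param fs Sampling rate, Hz (>= 50).
#' @param seed RNG seed.
#' @param n_clusters Number of cluster centres (up to 4).
#' @param base_spread Cluster SD in degrees at zero workload.
#' @param dispersion_gain Workload gain on cluster spread.
#' @param jitter_sd Within-fixation jitter SD, degrees.
#' @param dwell Dwell-time range, seconds.
#' @param min_jump Minimum distance between successive fixation targets,
#'   degrees.
#' @param fixation_share_gain Workload gain shortening dwells (0 =
#'   dwell distribution independent of load).
#' @param si_rate Base saccadic-intrusion rate, events/s.
#' @param si_rate_gain Workload gain on the SI rate.
#' @param si_amp SI amplitude range, degrees.
#' @param si_dur SI duration range, seconds (within 0.06-0.87).
#' @return A gaze [cwl_ts] (channels `gaze_x_deg`, `gaze_y_deg`) with
#'   attribute `truth`: planted fixations and SI events.
#' @export
gen_gaze <- function(workload, duration = 60, fs = 100, seed = 1,
                     n_clusters = 4, base_spread = 0.5, dispersion_gain = 2.5,
                     jitter_sd = 0.01, dwell = c(0.2, 0.8), min_jump = 1.2,
                     fixation_share_gain = 0,
                     si_rate = 0.2, si_rate_gain = 0,
                     si_amp = c(0.25, 0.4), si_dur = c(0.1, 0.3)) {
  stopifnot(fs >= 50, n_clusters >= 1, n_clusters <= nrow(.gaze_centers))
  .with_seed(seed, {
    spread <- base_spread * (1 + dispersion_gain * workload)
    p_switch <- min(0.35 + 0.45 * workload, 0.95)
    dwell_hi <- max(dwell[1] + 0.05,
                    dwell[2] / (1 + fixation_share_gain * workload))
    centers <- .gaze_centers[seq_len(n_clusters), , drop = FALSE]
    dt <- 1 / fs
    n <- round(duration * fs)
    x <- numeric(n); y <- numeric(n)
    f_start <- f_end <- f_dwell <- f_fx <- f_fy <- numeric()
    f_trunc <- logical()
    cl <- sample.int(n_clusters, 1)
    target <- centers[cl, ] + stats::rnorm(2, 0, spread)
    i <- 1L
    while (i <= n) {
      nd <- round(stats::runif(1, dwell[1], dwell_hi) * fs)
      j <- min(i + nd - 1L, n)
      x[i:j] <- target[1] + stats::rnorm(j - i + 1L, 0, jitter_sd)
      y[i:j] <- target[2] + stats::rnorm(j - i + 1L, 0, jitter_sd)
      f_start <- c(f_start, (i - 1) * dt); f_end <- c(f_end, (j - 1) * dt)
      f_dwell <- c(f_dwell, (j - i + 1L) * dt)
      f_fx <- c(f_fx, target[1]); f_fy <- c(f_fy, target[2])
      f_trunc <- c(f_trunc, j < i + nd - 1L)
      i <- j + 1L
      if (i > n) break
      if (stats::runif(1) < p_switch && n_clusters > 1) {
        cl <- sample(setdiff(seq_len(n_clusters), cl), 1)
      }
      for (try in 1:20) {
        new_target <- centers[cl, ] + stats::rnorm(2, 0, spread)
        if (sqrt(sum((new_target - target)^2)) >= min_jump) break
      }
      if (sqrt(sum((new_target - target)^2)) < min_jump) {
        gap <- new_target - target
        nrm <- sqrt(sum(gap^2))
        dir <- if (nrm > 0) gap / nrm else c(1, 0)
        new_target <- target + dir * min_jump
      }
      target <- new_target
    }
    fixations <- data.frame(start = f_start, end = f_end, dwell = f_dwell,
                            fx = f_fx, fy = f_fy, truncated = f_trunc)
    # plant saccadic intrusions inside sufficiently long fixations
    r_si <- si_rate * (1 + si_rate_gain * workload)
    n_si <- round(r_si * duration)
    s_onset <- s_dur <- s_amp <- numeric()
    if (n_si > 0) {
      margin <- 0.15  # settled baseline before onset, clear return after
      ok_fix <- which(fixations$dwell >= 2 * margin + si_dur[2])
      ok_fix <- ok_fix[sample.int(length(ok_fix),
                                  min(n_si, length(ok_fix)))]
      for (f in ok_fix) {
        amp <- stats::runif(1, si_amp[1], si_amp[2])
        m <- round(stats::runif(1, si_dur[1], si_dur[2]) * fs)
        i0 <- round(fixations$start[f] * fs) + 1L + round(margin * fs)
        idx <- i0:(i0 + m - 1L)
        x[idx] <- x[idx] + amp * sign(stats::runif(1) - 0.5)
        s_onset <- c(s_onset, (i0 - 1) * dt)
        s_dur <- c(s_dur, m * dt); s_amp <- c(s_amp, amp)
      }
    }
    si <- data.frame(onset = s_onset, duration = s_dur, amplitude = s_amp,
                     velocity = if (length(s_amp)) 2 * s_amp / s_dur
                                else numeric())
    t <- (seq_len(n) - 1) * dt
    out <- cwl_ts(t, data.frame(gaze_x_deg = x, gaze_y_deg = y), fs = fs,
                  units = c(gaze_x_deg = "deg", gaze_y_deg = "deg"))
    attr(out, "truth") <- list(fixations = fixations, si = si,
                               spread = spread, workload = workload)
    out
  })
}

#' Generate a synthetic multi-channel EEG recording
#'
#' Per channel: a shared set of band-limited sinusoid components (theta,
#' alpha, low beta, high beta) whose amplitudes scale as
#' `band_amps[b] * (1 + gains[b] * workload)`, a 1/f-amplitude background
#' unique to the channel, and white sensor noise. Channels get mildly
#' different gains on the shared part, emulating electrode placement.
#'
#' @param workload Scalar workload in `[0, 1]`.
#' @param duration Seconds.
#' @param fs Sampling rate, Hz (>= 64).
#' @param seed RNG seed.
#' @param channels Channel names (default the 5-electrode montage AF3,
#'   AF4, T7, T8, Pz).
#' @param band_amps Base per-band component amplitude, microvolts.
#' @param gains Per-band workload gains (see [default_gains()]).
#' @param background_rms RMS of the 1/f background, microvolts.
#' @param noise_sd White sensor-noise SD, microvolts.
#' @param n_comp Sinusoids per band.
#' @return An EEG [cwl_ts]; attribute `truth` records per-band component
#'   power.
#' @export
gen_eeg <- function(workload, duration = 60, fs = 128, seed = 1,
                    channels = c("AF3_uV", "AF4_uV", "T7_uV", "T8_uV", "Pz_uV"),
                    band_amps = c(theta = 2, alpha = 2.5,
                                  low_beta = 1.5, high_beta = 1),
                    gains = default_gains()$eeg,
                    background_rms = 2, noise_sd = 0.5, n_comp = 6) {
  stopifnot(fs >= 64)
  .with_seed(seed, {
    n <- round(duration * fs)
    t <- (seq_len(n) - 1) / fs
    bands <- eeg_bands()
    shared <- numeric(n)
    truth_power <- numeric(nrow(bands))
    names(truth_power) <- bands$band
    for (b in seq_len(nrow(bands))) {
      nm <- bands$band[b]
      hi <- min(bands$hi[b], 0.45 * fs)
      amp <- band_amps[[nm]] * (1 + gains[[nm]] * workload) / sqrt(n_comp)
      freqs <- stats::runif(n_comp, bands$lo[b] + 0.2, hi - 0.2)
      phases <- stats::runif(n_comp, 0, 2 * pi)
      for (i in seq_len(n_comp)) {
        shared <- shared + amp * sin(2 * pi * freqs[i] * t + phases[i])
      }
      truth_power[b] <- n_comp * amp^2 / 2
    }
    vals <- lapply(channels, function(ch) {
      g <- stats::runif(1, 0.9, 1.1)
      bg <- .one_over_f(n, fs, background_rms)
      g * shared + bg + stats::rnorm(n, 0, noise_sd)
    })
    names(vals) <- channels
    out <- cwl_ts(t, as.data.frame(vals), fs = fs)
    attr(out, "truth") <- list(band_power = truth_power, workload = workload)
    out
  })
}

# 1/f-amplitude noise via spectral synthesis, scaled to a target RMS
.one_over_f <- function(n, fs, rms) {
  if (rms <= 0) return(numeric(n))
  half <- floor(n / 2)
  f <- (seq_len(half)) * fs / n
  mag <- 1 / sqrt(pmax(f, 0.5))
  ph <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(half + 1)] <- spec
  if (n %% 2 == 0) {
    full[half + 1] <- complex(real = mag[half] * cos(ph[half]))
    full[seq(n, half + 2)] <- Conj(spec[seq_len(half - 1)])
  } else {
    full[seq(n, half + 2)] <- Conj(spec[seq_len(half - 1)])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

#' Generate synthetic inceptor and flight-state traces
#'
#' The inceptor alternates idle holds and active control bouts; the
#' active fraction is `base_activity + activity_gain * workload`
#' (capped at 0.95). Active bouts are random-rate ramps (rates uniform
#' on `rate_range` mm/s, direction random, reflected inside
#' `0.8 * delta_max`); idle bouts hold the deflection. Altitude and
#' airspeed follow their targets plus AR(1) errors whose stationary SD
#' scales with workload.
#'
#' @param workload Scalar workload in `[0, 1]`.
#' @param duration Seconds.
#' @param fs Sampling rate, Hz (>= 10).
#' @param seed RNG seed.
#' @param base_activity,activity_gain Active-fraction intercept and
#'   workload gain.
#' @param cycle Mean idle+active cycle length, seconds.
#' @param rate_range Active deflection-rate range, mm/s.
#' @param delta_max Full-scale deflection, mm.
#' @param noise_threshold Idle-rate threshold, mm/s.
#' @param alt_band Altitude task band, ft (target = midpoint).
#' @param alt_sd_base,alt_gain Altitude-error SD (ft) and workload gain.
#' @param speed_target Trim airspeed, knots.
#' @param speed_sd_base,speed_gain Airspeed-error SD (kt) and gain.
#' @param phi AR(1) coefficient of the tracking errors.
#' @return List with `inceptor` ([inceptor_trace]) and `flight`
#'   ([cwl_ts]); attribute `truth` records the active fraction.
#' @export
gen_inceptor_flight <- function(workload, duration = 60, fs = 20, seed = 1,
                                base_activity = 0.25, activity_gain = 0.5,
                                cycle = 5, rate_range = c(1, 5),
                                delta_max = 100, noise_threshold = 0.5,
                                alt_band = c(4000, 5000),
                                alt_sd_base = 40, alt_gain = 1.5,
                                speed_target = 120,
                                speed_sd_base = 3, speed_gain = 1.5,
                                phi = 0.98) {
  stopifnot(fs >= 10)
  .with_seed(seed, {
    a <- min(max(base_activity + activity_gain * workload, 0), 0.95)
    n <- round(duration * fs)
    dt <- 1 / fs
    t <- (seq_len(n) - 1) * dt
    # alternating bout activity mask with tight bout-length jitter so the
    # realised active fraction stays close to a
    active <- logical(n)
    pos <- 1L
    state <- stats::runif(1) < a
    while (pos <= n) {
      frac <- if (state) a else 1 - a
      if (frac <= 0) { state <- !state; next }  # skip empty bouts
      len <- max(1L, round(frac * cycle * stats::runif(1, 0.85, 1.15) * fs))
      end <- min(pos + len - 1L, n)
      active[pos:end] <- state
      pos <- end + 1L
      state <- !state
    }
    defl <- numeric(n)
    rate <- 0
    resample_every <- max(1L, round(0.5 * fs))
    for (i in 2:n) {
      if (active[i]) {
        if (i %% resample_every == 0 || !active[i - 1]) {
          rate <- stats::runif(1, rate_range[1], rate_range[2]) *
            sign(stats::runif(1) - 0.5)
        }
        cand <- defl[i - 1] + rate * dt
        if (abs(cand) > 0.8 * delta_max) {
          rate <- -rate
          cand <- defl[i - 1] + rate * dt
        }
        defl[i] <- cand
      } else {
        defl[i] <- defl[i - 1]
      }
    }
    inc <- inceptor_trace(t, defl, delta_max, noise_threshold)
    ar1 <- function(sd_target) {
      innov <- stats::rnorm(n, 0, sd_target * sqrt(1 - phi^2))
      as.numeric(stats::filter(innov, phi, method = "recursive"))
    }
    alt <- mean(alt_band) + ar1(alt_sd_base * (1 + alt_gain * workload))
    spd <- speed_target + ar1(speed_sd_base * (1 + speed_gain * workload))
    fl <- cwl_ts(t, data.frame(altitude_ft = alt, airspeed_kt = spd), fs = fs,
                 units = c(altitude_ft = "ft", airspeed_kt = "kt"))
    out <- list(inceptor = inc, flight = fl)
    attr(out, "truth") <- list(active_fraction = mean(active[-1]),
                               target_fraction = a, workload = workload)
    out
  })
}

#' Generate a synthetic n-back session log
#'
#' A stream of `n_trials` digit stimuli (1-9, one every `interval`
#' seconds). A trial is a target when the digit repeats the one `level`
#' steps back. Responses are scripted: targets draw a response with
#' probability `p_hit` (scored `correct`, else `missed`); non-targets
#' draw a spurious response with probability `p_false_alarm` (scored
#' `wrong`, else `avoid`).
#'
#' @param p_hit Hit probability on targets.
#' @param p_false_alarm False-alarm probability on non-targets.
#' @param n_trials Number of stimuli.
#' @param level The n of n-back (1-3).
#' @param seed RNG seed.
#' @param interval Stimulus onset asynchrony, seconds.
#' @return List with `events` (a `cwl_events` log of stimuli and
#'   responses), `counts` (a [confusion_counts]) and `stimuli`.
#' @export
gen_nback_log <- function(p_hit, p_false_alarm, n_trials = 30, level = 1,
                          seed = 1, interval = 2) {
  stopifnot(p_hit >= 0, p_hit <= 1, p_false_alarm >= 0, p_false_alarm <= 1,
            level >= 1)
  .with_seed(seed, {
    stim <- sample.int(9, n_trials, replace = TRUE)
    target <- rep(FALSE, n_trials)
    if (n_trials > level) {
      idx <- (level + 1):n_trials
      target[idx] <- stim[idx] == stim[idx - level]
    }
    respond <- ifelse(target, stats::runif(n_trials) < p_hit,
                      stats::runif(n_trials) < p_false_alarm)
    correct <- sum(target & respond)
    missed <- sum(target & !respond)
    wrong <- sum(!target & respond)
    avoid <- sum(!target & !respond)
    t_stim <- (seq_len(n_trials) - 1) * interval
    ev <- data.frame(
      t = c(t_stim, t_stim[respond] + stats::runif(sum(respond), 0.3, 1)),
      kind = c(rep("stimulus", n_trials), rep("response", sum(respond))),
      label = c(as.character(stim), rep("press", sum(respond))),
      stringsAsFactors = FALSE)
    ev <- ev[order(ev$t), ]
    rownames(ev) <- NULL
    class(ev) <- c("cwl_events", "data.frame")
    list(events = ev,
         counts = confusion_counts(correct, wrong, avoid, missed),
         stimuli = stim, n_targets = sum(target))
  })
}

#' Study configuration for the synthetic generator
#'
#' Defaults emulate a 12-participant, 3-condition repeated-measures
#' flight-simulator study: a baseline flying task (C1), an added
#' altitude-holding constraint (C2, slightly higher workload) and an
#' added secondary task (C3, markedly higher workload).
#'
#' @param participants Number of participants.
#' @param conditions Data frame with columns `name` and `workload`
#'   (each in `[0, 1]`).
#' @param duration Recording length per modality, seconds.
#' @param fs Named list of sampling rates: `gaze`, `eeg`, `inceptor`.
#' @param seed Master seed; every recording derives its own sub-seed
#'   from it, so the whole study is reproducible byte for byte.
#' @param gains Effect map, see [default_gains()].
#' @param subject_sd SD of the log-normal per-participant response
#'   multipliers (trait differences, constant across conditions).
#' @param blink_rate Blinks per minute in the pupil channels.
#' @return Object of class `cwl_study_config`.
#' @export
study_config <- function(participants = 12,
                         conditions = data.frame(
                           name = c("C1", "C2", "C3"),
                           workload = c(0.3, 0.45, 0.9)),
                         duration = 60,
                         fs = list(gaze = 100, eeg = 128, inceptor = 20),
                         seed = 1, gains = default_gains(),
                         subject_sd = 0.12, blink_rate = 0) {
  stopifnot(participants >= 2, nrow(conditions) >= 1,
            all(conditions$workload >= 0), all(conditions$workload <= 1))
  structure(list(participants = participants, conditions = conditions,
                 duration = duration, fs = fs, seed = seed, gains = gains,
                 subject_sd = subject_sd, blink_rate = blink_rate),
            class = "cwl_study_config")
}

# per-participant trait multipliers (same across conditions)
.subject_effects <- function(config, p) {
  .with_seed(.derive_seed(config$seed, p, 0), {
    list(pupil = exp(stats::rnorm(1, 0, config$subject_sd)),
         gaze = exp(stats::rnorm(1, 0, config$subject_sd)),
         eeg = exp(stats::rnorm(1, 0, config$subject_sd)),
         inceptor = stats::rnorm(1, 0, 0.03),
         tracking = exp(stats::rnorm(1, 0, config$subject_sd)))
  })
}

#' Generate one participant-condition recording set (in memory)
#'
#' @param config A [study_config()].
#' @param p Participant index (1-based).
#' @param ci Condition index (1-based).
#' @return List with `gaze` (combined gaze + pupil [cwl_ts]), `eeg`,
#'   `inceptor`, `flight`, `events` and `truth`.
#' @export
gen_recording_set <- function(config, p, ci) {
  w <- config$conditions$workload[ci]
  g <- config$gains
  sub <- .subject_effects(config, p)
  pup <- gen_pupil(w, config$duration, config$fs$gaze,
                   seed = .derive_seed(config$seed, p, ci, 1),
                   band_amp = 0.05 * sub$pupil, band_gain = g$pupil_band,
                   blink_rate = config$blink_rate)
  gz <- gen_gaze(w, config$duration, config$fs$gaze,
                 seed = .derive_seed(config$seed, p, ci, 2),
                 base_spread = 0.5 * sub$gaze, dispersion_gain = g$dispersion,
                 si_rate_gain = g$si_rate,
                 fixation_share_gain = g$fixation_share)
  eeg <- gen_eeg(w, config$duration, config$fs$eeg,
                 seed = .derive_seed(config$seed, p, ci, 3),
                 band_amps = c(theta = 2, alpha = 2.5, low_beta = 1.5,
                               high_beta = 1) * sub$eeg,
                 gains = g$eeg)
  ifl <- gen_inceptor_flight(w, config$duration, config$fs$inceptor,
                             seed = .derive_seed(config$seed, p, ci, 4),
                             base_activity = 0.25 + sub$inceptor,
                             activity_gain = g$inceptor,
                             alt_sd_base = 40 * sub$tracking,
                             speed_sd_base = 3 * sub$tracking,
                             alt_gain = g$tracking_error,
                             speed_gain = g$tracking_error)
  # merge pupil + gaze onto the common grid (same fs and duration)
  gaze_all <- cwl_ts(
    gz$t,
    data.frame(gaze_x_deg = gz$values$gaze_x_deg,
               gaze_y_deg = gz$values$gaze_y_deg,
               pupil_left_mm = pup$left$diameter,
               pupil_right_mm = pup$right$diameter),
    data.frame(gaze_x_deg = gz$valid$gaze_x_deg,
               gaze_y_deg = gz$valid$gaze_y_deg,
               pupil_left_mm = pup$left$valid,
               pupil_right_mm = pup$right$valid),
    fs = config$fs$gaze, units = .cwl_units$gaze)
  events <- data.frame(
    t = c(0, config$duration),
    kind = c("segment_start", "segment_end"),
    label = c("task", "task"), stringsAsFactors = FALSE)
  class(events) <- c("cwl_events", "data.frame")
  list(gaze = gaze_all, eeg = eeg, inceptor = ifl$inceptor,
       flight = ifl$flight, events = events,
       truth = list(workload = w,
                    pupil = attr(pup, "truth"),
                    gaze = attr(gz, "truth")[c("spread")],
                    si = attr(gz, "truth")$si,
                    eeg = attr(eeg, "truth")$band_power,
                    inceptor = attr(ifl, "truth")))
}

#' Generate a complete synthetic study
#'
#' One recording set per participant x condition. With `out_dir` the
#' study is written to disk in the CSV dialect [read_recording] reads
#' (`P01/C1/gaze.csv`, ...) together with a `manifest.json` recording
#' every true generating parameter; without it the study is returned in
#' memory.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory, or `NULL` for in-memory.
#' @param force Overwrite an existing non-empty `out_dir`?
#' @return Object of class `cwl_study`: list with `config`, `recordings`
#'   (named `P..>C..`; `NULL` entries when written to disk with
#'   `keep_in_memory = FALSE`), `dir`.
#' @param keep_in_memory Keep recordings in the returned object when
#'   writing to disk (default `FALSE` to bound memory).
#' @export
gen_study <- function(config = study_config(), out_dir = NULL, force = FALSE,
                      keep_in_memory = is.null(out_dir)) {
  to_disk <- !is.null(out_dir)
  if (to_disk) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
      stop(sprintf("output directory '%s' exists and is not empty; use force = TRUE",
                   out_dir), call. = FALSE)
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  recordings <- list()
  manifest <- list(participants = config$participants,
                   conditions = config$conditions,
                   duration = config$duration, fs = config$fs,
                   seed = config$seed, gains = config$gains,
                   subject_sd = config$subject_sd,
                   truth = list())
  for (p in seq_len(config$participants)) {
    pid <- sprintf("P%02d", p)
    for (ci in seq_len(nrow(config$conditions))) {
      cname <- config$conditions$name[ci]
      rec <- gen_recording_set(config, p, ci)
      key <- paste0(pid, ">", cname)
      manifest$truth[[key]] <- rec$truth[c("workload", "eeg", "inceptor")]
      if (to_disk) {
        d <- file.path(out_dir, pid, cname)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        write_recording(rec$gaze, file.path(d, "gaze.csv"), "gaze")
        write_recording(rec$eeg, file.path(d, "eeg.csv"), "eeg")
        inc_ts <- cwl_ts(rec$inceptor$t,
                         data.frame(defl_mm = rec$inceptor$defl),
                         fs = config$fs$inceptor)
        write_recording(inc_ts, file.path(d, "inceptor.csv"), "inceptor")
        write_recording(rec$flight, file.path(d, "flight.csv"), "flight")
        write_recording(rec$events, file.path(d, "events.csv"), "events")
      }
      recordings[[key]] <- if (keep_in_memory) rec else NULL
    }
  }
  if (to_disk) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(config = config,
                 recordings = if (keep_in_memory) recordings else NULL,
                 dir = if (to_disk) out_dir else NULL),
            class = "cwl_study")
}
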
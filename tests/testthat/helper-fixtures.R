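# Small in-code fixture builders shared across test files.

# a pupil epoch carrying a pure sinusoid on a constant baseline
sin_epoch <- function(freq, amp, duration = 10, fs = 100, baseline = 3,
                      eye = "left") {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  pupil_epoch(t, baseline + amp * sin(2 * pi * freq * t), eye, fs = fs)
}

# a gaze time series from explicit x (and optionally y) sample vectors
gaze_ts <- function(x, y = rep(0, length(x)), fs = 100,
                    valid = rep(TRUE, length(x))) {
  cwl_ts((seq_along(x) - 1) / fs,
         data.frame(gaze_x_deg = x, gaze_y_deg = y),
         data.frame(gaze_x_deg = valid, gaze_y_deg = valid),
         fs = fs)
}

# a full gaze-schema time series (gaze + pupil channels), constant pupil
gaze_schema_ts <- function(x, y = rep(0, length(x)), fs = 100) {
  n <- length(x)
  cwl_ts((seq_len(n) - 1) / fs,
         data.frame(gaze_x_deg = x, gaze_y_deg = y,
                    pupil_left_mm = rep(3, n), pupil_right_mm = rep(3, n)),
         fs = fs)
}

# uniform inceptor trace from deflections
defl_trace <- function(defl, fs = 10, delta_max = 100, noise_threshold = 0.5) {
  inceptor_trace((seq_along(defl) - 1) / fs, defl, delta_max, noise_threshold)
}

# study config with every workload gain zeroed (null study), scaled down
null_study_config <- function(seed, participants = 12, duration = 12) {
  study_config(
    participants = participants,
    conditions = data.frame(name = c("C1", "C2", "C3"),
                            workload = c(0.5, 0.5, 0.5)),
    duration = duration,
    fs = list(gaze = 50, eeg = 64, inceptor = 10),
    seed = seed,
    gains = list(pupil_band = 0, dispersion = 0,
                 eeg = c(theta = 0, alpha = 0, low_beta = 0, high_beta = 0),
                 inceptor = 0, tracking_error = 0,
                 si_rate = 0, fixation_share = 0))
}

# small monotone-workload config for fast pipeline tests
small_study_config <- function(seed, participants = 6, duration = 10) {
  study_config(participants = participants,
               duration = duration,
               fs = list(gaze = 50, eeg = 64, inceptor = 10),
               seed = seed)
}
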
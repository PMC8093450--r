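test_that("blink preprocessing interpolates short gaps and rejects sparse epochs", {
  fs <- 100
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  d <- 3 + 0.1 * sin(2 * pi * 2 * t)
  valid <- rep(TRUE, length(t))
  valid[301:310] <- FALSE  # 100 ms blink
  ep <- pupil_epoch(t, d, "left", fs = fs, valid = valid)
  out <- preprocess_pupil(ep)
  expect_length(out, 1)
  expect_length(out[[1]]$t, length(t))
  expect_false(anyNA(out[[1]]$diameter))

  # fully valid epoch passes through unchanged
  ep2 <- pupil_epoch(t, d, "left", fs = fs)
  out2 <- preprocess_pupil(ep2)
  expect_equal(out2[[1]]$diameter, d, tolerance = 1e-9)

  # 60% invalid is rejected with a classed condition
  valid3 <- rep(FALSE, length(t)); valid3[seq_len(0.4 * length(t))] <- TRUE
  expect_error(preprocess_pupil(pupil_epoch(t, d, "left", fs, valid3)),
               class = "cwl_epoch_rejected")

  # a gap longer than 500 ms splits the epoch
  valid4 <- rep(TRUE, length(t)); valid4[401:480] <- FALSE
  out4 <- preprocess_pupil(pupil_epoch(t, d, "left", fs, valid4))
  expect_length(out4, 2)
})

test_that("L1NS recovers a band sinusoid's amplitude and is linear", {
  ep <- sin_epoch(3, 0.2)
  expect_equal(l1ns(ep), 0.2, tolerance = 0.005)
  expect_equal(l1ns(sin_epoch(3, 0.4)), 2 * l1ns(ep), tolerance = 1e-6)
  expect_equal(l1ns(sin_epoch(3, 0.2, baseline = 5)), l1ns(ep),
               tolerance = 1e-9)  # translation invariance
  # constant epoch
  t <- seq(0, 9.99, by = 0.01)
  expect_equal(l1ns(pupil_epoch(t, rep(3, length(t)), "left", fs = 100)), 0)
  expect_error(l1ns(sin_epoch(3, 0.2, duration = 1)), "too short")
})

test_that("L1NS is insensitive to slow luminance drift below 0.2 Hz", {
  fs <- 100
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  base <- 3 + 0.2 * sin(2 * pi * 3 * t)
  ref <- l1ns(pupil_epoch(t, base, "left", fs = fs))
  set.seed(7)
  for (fd in c(0.05, 0.11, 0.19)) {
    drift <- 0.3 * sin(2 * pi * fd * t + runif(1, 0, 2 * pi))
    withdrift <- l1ns(pupil_epoch(t, base + drift, "left", fs = fs))
    expect_lt(abs(withdrift - ref) / ref, 0.02)
  }
})

test_that("L1NS grows strictly with 1-5 Hz component power", {
  vals <- vapply(c(0.05, 0.1, 0.2, 0.4), function(a) l1ns(sin_epoch(2.5, a)),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("STDP follows the sample convention and scales with |c|", {
  expect_equal(stdp(pupil_epoch(c(0, 0.01), c(2, 4), fs = 100)), sqrt(2))
  t <- seq(0, 1, by = 0.01)
  ep <- pupil_epoch(t, 3 + rnorm(length(t), 0, 0.1), fs = 100)
  ep3 <- ep; ep3$diameter <- ep$diameter * -2.5
  expect_equal(stdp(ep3), 2.5 * stdp(ep))
  expect_equal(stdp(pupil_epoch(t, rep(3, length(t)), fs = 100)), 0)
  expect_error(stdp(pupil_epoch(0, 3, fs = 100)), "2 samples")
})

test_that("LPF metric passes the band and rejects the stopband", {
  a <- 0.5
  expect_equal(lpf_metric(sin_epoch(1, a)), 2 * a / pi, tolerance = 0.01)
  expect_lt(lpf_metric(sin_epoch(20, a)), 0.01 * a)
  t <- seq(0, 9.99, by = 0.01)
  expect_equal(lpf_metric(pupil_epoch(t, rep(3, length(t)), fs = 100)), 0)
  expect_equal(lpf_metric(sin_epoch(1, a, baseline = 7)),
               lpf_metric(sin_epoch(1, a)), tolerance = 1e-9)
  expect_error(lpf_metric(sin_epoch(1, a), cutoff = 60), "Nyquist")
})
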
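test_that("duty cycle separates idle holds from active control", {
  expect_equal(duty_cycle(defl_trace(rep(5, 101))), 0)
  ramp <- defl_trace(2 * (0:100) / 10)  # 2 mm/s everywhere
  expect_equal(duty_cycle(ramp), 100)

  # active during exactly the first half of the trace
  fs <- 10
  d <- c(2 * (0:50) / fs, rep(10, 50))
  dc <- duty_cycle(defl_trace(d, fs = fs))
  expect_lt(abs(dc - 50), 100 / length(d) + 1e-9)

  # time-shift invariance
  tr <- defl_trace(c(rep(0, 20), 1.5 * (0:30) / 10, rep(4.5, 20)))
  tr2 <- tr; tr2$t <- tr$t + 123.4
  expect_equal(duty_cycle(tr), duty_cycle(tr2))
  expect_true(duty_cycle(tr) >= 0 && duty_cycle(tr) <= 100)

  # per-sample mode reproduces the raw count / elapsed-time expression
  x_manual <- as.numeric(!(abs(diff(d)) * fs < 0.5 & abs(d[-1]) < 100))
  expect_equal(duty_cycle(defl_trace(d, fs = fs), method = "per_sample"),
               100 * sum(x_manual) / (d_t <- (length(d) - 2) / fs))
  expect_error(duty_cycle(defl_trace(c(0, 1))), "3 samples")
})

test_that("aggressiveness is the mean squared deflection rate", {
  ramp <- defl_trace(2 * (0:100) / 10)
  expect_equal(aggressiveness(ramp), 4)
  expect_equal(aggressiveness(defl_trace(rep(7, 50))), 0)
  set.seed(3)
  d <- cumsum(rnorm(100, 0, 0.3))
  tr <- defl_trace(d)
  tr_scaled <- defl_trace(2.5 * d)
  expect_equal(aggressiveness(tr_scaled), 2.5^2 * aggressiveness(tr),
               tolerance = 1e-12)
  tr_off <- defl_trace(d + 10)
  expect_equal(aggressiveness(tr_off), aggressiveness(tr), tolerance = 1e-12)
})

test_that("duty cycle recovers the generated activity fraction", {
  for (a in c(0.2, 0.5, 0.8)) {
    w <- (a - 0.25) / 0.5
    g <- gen_inceptor_flight(w, duration = 60, fs = 20, seed = 13)
    expect_lt(abs(duty_cycle(g$inceptor) - 100 * a), 5)
  }
  idle <- gen_inceptor_flight(0, duration = 30, fs = 20, seed = 1,
                              base_activity = 0, activity_gain = 0)
  expect_equal(duty_cycle(idle$inceptor), 0)
  expect_lt(aggressiveness(idle$inceptor), 1e-12)
})

test_that("percentage RMSE is the normalised deviation from the reference", {
  n <- 200
  t <- (0:(n - 1)) / 20
  at_target <- cwl_ts(t, data.frame(altitude_ft = rep(4500, n),
                                    airspeed_kt = rep(120, n)), fs = 20)
  expect_equal(rmse_percent(at_target, "altitude"), 0)
  expect_equal(rmse_percent(at_target, "airspeed"), 0)

  off <- cwl_ts(t, data.frame(altitude_ft = rep(4500 + 250, n),
                              airspeed_kt = rep(120 + 6, n)), fs = 20)
  expect_equal(rmse_percent(off, "altitude"), 100 * 250 / 4500)
  expect_equal(rmse_percent(off, "airspeed"), 100 * 6 / 120)

  # monotone in the error SD
  set.seed(8)
  rms <- vapply(c(10, 50, 150), function(s) {
    mean(replicate(8, {
      fl <- cwl_ts(t, data.frame(altitude_ft = 4500 + rnorm(n, 0, s),
                                 airspeed_kt = rep(120, n)), fs = 20)
      rmse_percent(fl, "altitude")
    }))
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})
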
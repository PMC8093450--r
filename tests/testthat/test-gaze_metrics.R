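test_that("I-VT separates fixations and saccades by velocity", {
  # static gaze: one fixation, no saccades
  fx <- ivt_classify(gaze_schema_ts(rep(0, 100)))
  expect_equal(fx$n, 1)
  expect_equal(nrow(fx$saccades), 0)

  # 300 ms at (0,0), one-sample 5 deg jump, 300 ms at (5,0) @ 100 Hz
  x <- c(rep(0, 30), 2.5, rep(5, 30))
  fx2 <- ivt_classify(gaze_schema_ts(x))
  expect_equal(fx2$n, 2)
  expect_equal(nrow(fx2$saccades), 1)
  expect_equal(fx2$fixations$fx, c(0, 5), tolerance = 1e-9)

  # threshold above the jump velocity: one fixation spans everything
  fx3 <- ivt_classify(gaze_schema_ts(x), velocity_threshold = 1000)
  expect_equal(fx3$n, 1)
  expect_equal(nrow(fx3$saccades), 0)

  # all-invalid input: empty set with a warning
  ts <- gaze_ts(rep(0, 50), valid = rep(FALSE, 50))
  expect_warning(fx4 <- ivt_classify(ts), "invalid")
  expect_equal(fx4$n, 0)
})

test_that("I-VT sample classes partition the valid samples", {
  gz <- gen_gaze(0.6, duration = 20, fs = 100, seed = 3)
  fx <- ivt_classify(gz)
  cls <- table(fx$sample_class)
  expect_equal(sum(cls[c("fixation", "saccade", "discarded")]),
               sum(gz$valid$gaze_x_deg))
  expect_equal(unname(cls["invalid"]), sum(!gz$valid$gaze_x_deg))
  # fixation time from events equals fixation-classified sample time
  expect_equal(sum(fx$fixations$duration),
               unname(cls["fixation"]) * fx$dt, tolerance = 1e-9)
})

test_that("fixation and saccade rates are simple ratios", {
  fset <- data.frame(duration = c(1, 2))
  expect_equal(fixation_rate(fset, duration = 4), 0.75)
  expect_equal(fixation_rate(data.frame(duration = numeric()), duration = 4), 0)
  expect_equal(fixation_rate(data.frame(duration = 4), duration = 4), 1)
  expect_error(fixation_rate(fset, duration = 0), "positive")
  sac <- data.frame(start = 1:4)
  expect_equal(saccade_rate(sac, duration = 2), 2)
  expect_equal(saccade_rate(sac, duration = 4), 1)
  expect_equal(saccade_rate(sac[0, , drop = FALSE], duration = 2), 0)
})

test_that("NNI matches the closed form and is scale invariant", {
  sq <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  r <- nni(sq)
  expect_equal(r$d_nn, 1)
  expect_equal(r$d_mrd, 0.25)
  expect_equal(r$nni, 4)
  r2 <- nni(sq * 3.7)
  expect_equal(r2$nni, 4, tolerance = 1e-12)
  expect_warning(r3 <- nni(matrix(1, 5, 2)), "degenerate")
  expect_equal(r3$nni, 0)
  expect_error(nni(sq[1, , drop = FALSE]), "2 points")
})

test_that("uniform scatter gives NNI near 1 and clusters score lower", {
  set.seed(11)
  unif <- replicate(20, nni(cbind(runif(300), runif(300)))$nni)
  expect_lt(abs(mean(unif) - 1), 0.1)
  clus <- replicate(20, {
    centers <- matrix(runif(8), 4, 2)
    pts <- centers[sample(4, 300, TRUE), ] + matrix(rnorm(600, 0, 0.01), 300, 2)
    nni(pts)$nni
  })
  expect_lt(t.test(clus, unif, alternative = "less")$p.value, 0.01)
})

test_that("saccadic intrusions follow the out-and-back definition", {
  fs <- 100
  # plateau excursion to 1 deg returning after 200 ms
  x <- rep(0, 300); x[101:120] <- 1
  si <- detect_si(x, fs = fs)
  expect_equal(nrow(si), 1)
  expect_equal(si$amplitude, 1)
  expect_equal(si$duration, 0.2)
  expect_equal(si$velocity, 10)

  # return after 1000 ms is outside the 60-870 ms window
  x2 <- rep(0, 400); x2[101:200] <- 1
  expect_equal(nrow(detect_si(x2, fs = fs)), 0)

  # flat trace has no events; a short epoch warns
  expect_equal(nrow(detect_si(rep(0, 300), fs = fs)), 0)
  expect_warning(detect_si(rep(0, 50), fs = fs), "shorter")
})

test_that("planted intrusions are recovered with faithful velocities", {
  gz <- gen_gaze(0.4, duration = 40, fs = 100, seed = 21, si_rate = 0.25)
  truth <- attr(gz, "truth")$si
  si <- detect_si(gz)
  matched <- vapply(truth$onset,
                    function(o) any(abs(si$onset - o) < 0.05), logical(1))
  expect_gte(mean(matched), 0.9)
  expect_lt(abs(median_si_velocity(si) - median(truth$velocity)) /
              median(truth$velocity), 0.15)
})

test_that("median SI velocity summarises events and handles emptiness", {
  ev <- data.frame(velocity = c(5, 10, 20))
  expect_equal(median_si_velocity(ev), 10)
  expect_equal(median_si_velocity(data.frame(velocity = 7)), 7)
  expect_true(is.na(median_si_velocity(ev[0, , drop = FALSE])))
  expect_true(is.na(median_si_velocity(NULL)))
})
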
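test_that("outer fences match the hand-computed quartile convention", {
  f <- outer_fence_filter(c(1, 2, 3, 4, 100))
  expect_equal(unname(f$fences), c(-4, 10))
  expect_equal(f$kept, c(1, 2, 3, 4))
  expect_equal(f$removed_mask, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("outer fencing keeps all-equal vectors and nearly all Gaussian data", {
  x <- rep(5, 10)
  expect_length(outer_fence_filter(x)$kept, 10)
  set.seed(101)
  g <- rnorm(1000)
  f <- outer_fence_filter(g)
  expect_lt(mean(f$removed_mask), 0.01)
  # idempotence: filtering the kept set removes nothing more
  expect_length(outer_fence_filter(f$kept)$kept, length(f$kept))
  expect_error(outer_fence_filter(c(1, 2, NA, NA, NA)), "4 finite")
})

test_that("recording round-trips through the CSV schemas", {
  n <- 30
  ts <- cwl_ts((0:(n - 1)) / 100,
               data.frame(gaze_x_deg = rnorm(n), gaze_y_deg = rnorm(n),
                          pupil_left_mm = runif(n, 2, 4),
                          pupil_right_mm = runif(n, 2, 4)),
               fs = 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(ts, path, "gaze")
  back <- read_recording(path, "gaze")
  expect_s3_class(back, "cwl_ts")
  expect_equal(names(back$values),
               c("gaze_x_deg", "gaze_y_deg", "pupil_left_mm", "pupil_right_mm"))
  expect_equal(back$values$pupil_left_mm, ts$values$pupil_left_mm,
               tolerance = 1e-10)
  expect_true(all(unlist(back$valid)))
})

test_that("schema violations are reported by name and row", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(t_s = c(0, 0.01, 0.02), gaze_x_deg = 0, gaze_y_deg = 0,
                   pupil_right_mm = 3, valid_left = TRUE, valid_right = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_recording(path, "gaze"), "pupil_left_mm")
  df2 <- data.frame(t_s = c(0, 0.01, 0.01, 0.03), defl_mm = 0)
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(read_recording(path, "inceptor"), "row 3")
})

test_that("event segmentation spans closed intervals and preserves samples", {
  n <- 1000
  ts <- cwl_ts((0:(n - 1)) / 100, data.frame(defl_mm = rnorm(n)), fs = 100)
  ev <- data.frame(t = c(2, 5), kind = c("segment_start", "segment_end"),
                   label = c("task", "task"))
  class(ev) <- c("cwl_events", "data.frame")
  segs <- segment_by_events(ts, ev, "task")
  expect_length(segs, 1)
  expect_equal(ts_duration(segs[[1]]), 3, tolerance = 0.02)
  # boundary samples included
  expect_equal(min(segs[[1]]$t), 2)
  expect_equal(max(segs[[1]]$t), 5)

  ev2 <- data.frame(t = c(1, 2, 7, 8),
                    kind = rep(c("segment_start", "segment_end"), 2),
                    label = "task")
  class(ev2) <- c("cwl_events", "data.frame")
  segs2 <- segment_by_events(ts, ev2, "task")
  expect_length(segs2, 2)
  expect_lt(max(segs2[[1]]$t), min(segs2[[2]]$t))
  # union of segment samples + discarded = original sample count
  in_seg <- (ts$t >= 1 & ts$t <= 2) | (ts$t >= 7 & ts$t <= 8)
  expect_equal(length(segs2[[1]]$t) + length(segs2[[2]]$t), sum(in_seg))

  ev3 <- data.frame(t = c(9, 12), kind = c("segment_start", "segment_end"),
                    label = "task")
  class(ev3) <- c("cwl_events", "data.frame")
  expect_warning(segs3 <- segment_by_events(ts, ev3, "task"), "truncated")
  expect_equal(max(segs3[[1]]$t), max(ts$t))
  expect_warning(none <- segment_by_events(ts, ev, "nope"), "no segment")
  expect_length(none, 0)
})

test_that("resampling yields a uniform grid through gaps", {
  t <- c(0, 0.01, 0.02, 0.05, 0.06)
  ts <- cwl_ts(t, data.frame(v = c(0, 1, 2, 5, 6)), fs = 100)
  r <- ts_resample(ts, 100)
  expect_equal(diff(r$t), rep(0.01, length(r$t) - 1), tolerance = 1e-9)
  expect_equal(r$values$v, 0:6 * 1, tolerance = 1e-9)
})
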
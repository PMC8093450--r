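test_that("every generator is deterministic in its seed", {
  p1 <- gen_pupil(0.5, 5, 100, seed = 9); p2 <- gen_pupil(0.5, 5, 100, seed = 9)
  expect_identical(p1$left$diameter, p2$left$diameter)
  g1 <- gen_gaze(0.5, 5, 100, seed = 9); g2 <- gen_gaze(0.5, 5, 100, seed = 9)
  expect_identical(g1$values, g2$values)
  e1 <- gen_eeg(0.5, 5, 128, seed = 9); e2 <- gen_eeg(0.5, 5, 128, seed = 9)
  expect_identical(e1$values, e2$values)
  f1 <- gen_inceptor_flight(0.5, 5, 20, seed = 9)
  f2 <- gen_inceptor_flight(0.5, 5, 20, seed = 9)
  expect_identical(f1$inceptor$defl, f2$inceptor$defl)
  # different seeds differ
  expect_false(identical(p1$left$diameter,
                         gen_pupil(0.5, 5, 100, seed = 10)$left$diameter))
})

test_that("pupil generator modulates the 1-5 Hz band with workload", {
  l0 <- vapply(1:20, function(s) l1ns(gen_pupil(0, 20, 100, seed = s)$left),
               numeric(1))
  l1 <- vapply(1:20, function(s) l1ns(gen_pupil(1, 20, 100, seed = 100 + s)$left),
               numeric(1))
  expect_lt(t.test(l0, l1, alternative = "less")$p.value, 0.01)
  # silent generator: no band component, no noise
  quiet <- gen_pupil(0, 10, 100, seed = 1, band_amp = 0, noise_sd = 0,
                     drift_amp = 0)
  expect_lt(l1ns(quiet$left), 1e-10)
  # left and right eyes track each other
  p <- gen_pupil(0.5, 30, 100, seed = 4)
  expect_gt(cor(p$left$diameter, p$right$diameter), 0.8)
})

test_that("gaze generator produces lawful dwells, intrusions and dispersion", {
  gz <- gen_gaze(0.5, 30, 100, seed = 5, si_rate = 0.3)
  truth <- attr(gz, "truth")
  dw <- truth$fixations$dwell[!truth$fixations$truncated]
  expect_true(all(dw >= 0.2 - 1e-9 & dw <= 0.8 + 1e-9))
  expect_true(all(truth$si$duration >= 0.06 & truth$si$duration <= 0.87))
  expect_true(all(truth$si$amplitude > 0.1))
  # dispersion rises with workload
  n0 <- vapply(1:15, function(s)
    nni(ivt_classify(gen_gaze(0, 20, 100, seed = s)))$nni, numeric(1))
  n1 <- vapply(1:15, function(s)
    nni(ivt_classify(gen_gaze(1, 20, 100, seed = 200 + s)))$nni, numeric(1))
  expect_lt(t.test(n0, n1, alternative = "less")$p.value, 0.01)
})

test_that("EEG generator scales band power with the effect map", {
  e0 <- gen_eeg(0, 20, 128, seed = 3)
  e1 <- gen_eeg(1, 20, 128, seed = 303)
  b0 <- band_power_summary(e0)$median
  b1 <- band_power_summary(e1)$median
  for (b in c("theta", "low_beta")) {
    expect_gt(b1$power[b1$band == b], b0$power[b0$band == b])
  }
  # the 5-channel montage is emitted
  expect_equal(names(e0$values), c("AF3_uV", "AF4_uV", "T7_uV", "T8_uV", "Pz_uV"))
})

test_that("inceptor/flight generator scales activity and tracking error", {
  r0 <- vapply(1:12, function(s)
    rmse_percent(gen_inceptor_flight(0, 30, 20, seed = s)$flight, "altitude"),
    numeric(1))
  r1 <- vapply(1:12, function(s)
    rmse_percent(gen_inceptor_flight(1, 30, 20, seed = 400 + s)$flight, "altitude"),
    numeric(1))
  expect_lt(t.test(r0, r1, alternative = "less")$p.value, 0.01)
})

test_that("n-back logs tally into the accuracy formula", {
  perfect <- gen_nback_log(1, 0, n_trials = 50, level = 2, seed = 6)
  expect_equal(accuracy_nback(perfect$counts), 1)
  cts <- perfect$counts
  expect_equal(cts$correct + cts$wrong + cts$avoid + cts$missed, 50)
  # expected accuracy under known hit/false-alarm rates
  g <- gen_nback_log(0.8, 0.1, n_trials = 500, level = 1, seed = 7)
  n_t <- g$n_targets; n_nt <- 500 - n_t
  expected <- (0.8 * n_t + 0.9 * n_nt) / 500
  obs <- accuracy_nback(g$counts)
  expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / 500))
  # stimulus events arrive every 2 s
  stim_t <- g$events$t[g$events$kind == "stimulus"]
  expect_equal(diff(sort(stim_t)), rep(2, 499))
})

test_that("a written study round-trips its manifest and is byte-reproducible", {
  cfg <- small_study_config(seed = 77, participants = 3, duration = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen_study(cfg, out_dir = file.path(d1, "study"))
  gen_study(cfg, out_dir = file.path(d2, "study"))
  man <- jsonlite::read_json(file.path(d1, "study", "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$participants, 3)
  expect_equal(man$seed, 77)
  expect_equal(man$conditions$name, c("C1", "C2", "C3"))
  f1 <- list.files(file.path(d1, "study"), recursive = TRUE)
  f2 <- list.files(file.path(d2, "study"), recursive = TRUE)
  expect_equal(f1, f2)
  expect_length(f1, 3 * 3 * 5 + 1)  # 5 CSVs per cell + manifest
  h1 <- tools::md5sum(file.path(d1, "study", f1))
  h2 <- tools::md5sum(file.path(d2, "study", f2))
  expect_equal(unname(h1), unname(h2))
  # refuses to clobber without force
  expect_error(gen_study(cfg, out_dir = file.path(d1, "study")), "force")
  expect_silent(gen_study(cfg, out_dir = file.path(d1, "study"), force = TRUE))
})
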
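test_that("a jitter-free 60 bpm train has unit RR spacing and 10 beats in 10 s", {
  r <- synth_single_ecg(60, 10, 250, rr_jitter_pct = 0, seed = 1)
  pk <- r$rpeaks_maternal
  expect_true(length(pk) %in% c(10L, 11L))
  expect_true(all(diff(pk) == 250L))
  # annotations sit on local maxima of the waveform (clean, no jitter)
  x <- r$signals[, 1]
  for (p in pk[pk > 2 & pk < length(x) - 1])
    expect_true(x[p] >= x[p - 1] - 1e-9 && x[p] >= x[p + 1] - 1e-9)
})

test_that("generator is deterministic and honours degenerate morphology", {
  a <- synth_single_ecg(120, 8, 250, seed = 42)
  b <- synth_single_ecg(120, 8, 250, seed = 42)
  expect_identical(a$signals, b$signals)
  expect_identical(a$rpeaks_maternal, b$rpeaks_maternal)
  m <- beat_morphology()
  m$wave_amplitudes[] <- 0
  z <- synth_single_ecg(100, 5, 250, morphology = m, seed = 1)
  expect_true(all(z$signals == 0))
  expect_gt(length(z$rpeaks_maternal), 0)
  expect_error(synth_single_ecg(300, 5, 250), "heart rate")
})

test_that("morphology validation rejects malformed wave sets", {
  expect_error(beat_morphology(wave_widths = c(0, 1, 1, 1, 1) * 0.01), "positive")
  expect_error(beat_morphology(wave_amplitudes = c(2, -0.1, 1, -0.2, 0.3)),
               "R wave")
  expect_error(beat_morphology(wave_centers = c(0.1, -0.05, 0, 0.05, 0.3)),
               "ordered")
})

test_that("noise-free mixing is exactly additive and ratio-calibrated", {
  sp <- scenario_spec("C0", noise_snr_db = NA, duration_s = 20, seed = 5)
  m <- synth_single_ecg(80, 20, 250, morphology = maternal_morphology(),
                        seed = 5, role = "maternal_truth")
  f <- synth_single_ecg(140, 20, 250, morphology = fetal_morphology(),
                        seed = 6, role = "fetal_truth")
  rec <- mix_abdominal(m, f, sp)
  mix <- record_channel(rec, "abdominal_mixture")
  mt <- record_channel(rec, "maternal_truth")
  ft <- record_channel(rec, "fetal_truth")
  expect_equal(mix, mt + ft, tolerance = 1e-12)
  ratio <- median(abs(ft[rec$rpeaks_fetal])) /
    median(abs(mt[rec$rpeaks_maternal]))
  expect_close(ratio, 0.25, 0.02)
})

test_that("noise power is calibrated within 0.1 dB at all five levels", {
  for (lvl in c(0, 3, 6, 9, 12)) {
    rec <- quick_record(20, seed = 7 + lvl, noise = lvl)
    ft <- record_channel(rec, "fetal_truth")
    nz <- rec$meta$noise
    achieved <- 10 * log10(mean(ft^2) / mean(nz^2))
    expect_close(achieved, lvl, 0.1)
  }
})

test_that("mixture minus truth channels equals the injected noise exactly", {
  for (scen in c("C0", "C1", "C3", "C4", "C5-stub")) {
    rec <- quick_record(20, seed = 31, scenario = scen)
    resid <- record_channel(rec, "abdominal_mixture") -
      record_channel(rec, "maternal_truth") -
      record_channel(rec, "fetal_truth")
    expect_lt(max(abs(resid - rec$meta$noise)), 1e-9)
  }
})

test_that("fetal annotations coincide with fetal waveform maxima (clean case)", {
  sp <- scenario_spec("C0", noise_snr_db = NA, duration_s = 15, seed = 9,
                      rr_jitter_pct = 0)
  rec <- simulate_record(sp)
  ft <- abs(record_channel(rec, "fetal_truth"))
  for (p in rec$rpeaks_fetal) {
    lo <- max(1, p - 1); hi <- min(length(ft), p + 1)
    expect_true(ft[p] >= max(ft[lo:hi]) - 1e-9)
  }
})

test_that("C0 applies no event beyond the additive noise", {
  sp <- scenario_spec("C0", noise_snr_db = 6, duration_s = 15, seed = 12)
  m <- synth_single_ecg(80, 15, 250, morphology = maternal_morphology(),
                        seed = 12, role = "maternal_truth")
  f <- synth_single_ecg(140, 15, 250, morphology = fetal_morphology(),
                        seed = 13, role = "fetal_truth")
  mixed <- mix_abdominal(m, f, sp)
  after <- apply_scenario_events(mixed, sp)
  expect_equal(record_channel(after, "maternal_truth"),
               record_channel(mixed, "maternal_truth"))
  expect_equal(record_channel(after, "fetal_truth"),
               record_channel(mixed, "fetal_truth"))
  bad <- sp; bad$scenario <- "C9"
  expect_error(apply_scenario_events(mixed, bad), "unknown scenario")
})

test_that("C2 ramps the fetal rate by the requested factor", {
  sp <- scenario_spec("C2", noise_snr_db = 6, duration_s = 60, seed = 21,
                      fetal_hr_bpm = 120,
                      hr_modulation = list(target = "fetal", hr_to = 160))
  rec <- simulate_record(sp)
  pk <- rec$rpeaks_fetal / rec$fs
  rr_first <- mean(diff(pk[pk < 10]))
  rr_last <- mean(diff(pk[pk > 50]))
  implied <- rr_first / rr_last
  # instantaneous rate ratio at the end of a 0->full linear ramp vs start
  expect_close(implied, 160 / 120, 0.05 * 160 / 120)
})

test_that("C4 inserts a Poisson-consistent number of flagged ectopic beats", {
  sp <- scenario_spec("C4", noise_snr_db = 6, duration_s = 60, seed = 77,
                      ectopic_rate = 6)
  rec <- simulate_record(sp)
  k <- length(rec$meta$ectopic_fetal)
  expect_gt(k, 0)
  expect_lt(k, 6 + 5 * sqrt(6) + 1)       # rate*duration +- Poisson spread
  expect_true(all(rec$meta$ectopic_fetal %in% rec$rpeaks_fetal))
})

test_that("the twin stub adds a second distinguishable fetal peak train", {
  rec <- quick_record(30, seed = 15, scenario = "C5-stub")
  twin <- rec$meta$rpeaks_fetal_twin
  expect_gt(length(twin), 0)
  # the twin runs at a distinct (higher) rate than the primary fetus
  rate1 <- length(rec$rpeaks_fetal) - 1
  rate2 <- length(twin) - 1
  expect_gt(rate2, rate1 * 1.05)
})

test_that("datasets are enumerable, reproducible and manifest-driven", {
  dir <- withr::local_tempdir()
  specs <- list(scenario_spec("C0", noise_snr_db = 6, duration_s = 10,
                              seed = 50))
  man <- make_dataset(2, specs, dir)
  expect_equal(nrow(man), 2)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  recs <- load_dataset(dir)
  expect_length(recs, 2)
  # regenerate into a second directory: byte-identical signals
  dir2 <- withr::local_tempdir()
  make_dataset(2, specs, dir2)
  for (nm in list.files(dir, pattern = "\\.csv$"))
    expect_identical(readLines(file.path(dir, nm)),
                     readLines(file.path(dir2, nm)))
  # the full study grid enumerates 7 scenarios x 5 noise levels
  grid <- scenario_grid(duration_s = 10)
  expect_length(grid, 35)
})
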
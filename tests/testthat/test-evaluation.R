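test_that("signal metrics follow their closed forms", {
  y <- rnorm(500)
  perfect <- signal_metrics(y, y)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$snr_db, Inf)
  # halving the signal leaves a residual of half power ratio 4 : 6.021 dB
  half <- signal_metrics(y, y / 2)
  expect_equal(half$snr_db, 10 * log10(4), tolerance = 1e-9)
  hand <- signal_metrics(c(1, -1), c(0, 0))
  expect_equal(hand$mse, 1)
  expect_equal(hand$mae, 1)
  expect_equal(hand$snr_db, 0)
  expect_error(signal_metrics(c(0, 0), c(1, 1)), "all-zero")
  expect_error(signal_metrics(y, y[-1]), "length")
})

test_that("SNR decreases monotonically with added noise power", {
  set.seed(2)
  y <- rnorm(2000)
  snrs <- vapply(c(0.1, 0.3, 1, 3), function(s)
    signal_metrics(y, y + rnorm(2000, sd = s))$snr_db, numeric(1))
  expect_true(all(diff(snrs) < 0))
})

test_that("Pan-Tompkins finds nearly every clean beat for both profiles", {
  f <- synth_single_ecg(140, 60, 250, morphology = fetal_morphology(),
                        rr_jitter_pct = 3, seed = 5, role = "fetal_truth")
  pk <- pan_tompkins(f$signals[, 1], 250, "fetal")
  ds <- detection_scores(match_peaks(pk, f$rpeaks_fetal, 250))
  expect_gte(ds$se_pct, 99)
  expect_gte(ds$ppv_pct, 99)
  m <- synth_single_ecg(80, 60, 250, morphology = maternal_morphology(),
                        rr_jitter_pct = 3, seed = 6, role = "maternal_truth")
  pkm <- pan_tompkins(m$signals[, 1], 250, "maternal")
  expect_lte(abs(length(pkm) - 80), 1)     # ~80 beats in 60 s at 80 bpm
  expect_identical(pan_tompkins(numeric(5000), 250, "fetal"), integer())
  expect_error(pan_tompkins(rnorm(100), 250), "2 s")
})

test_that("peak matching books TPs, FPs and FNs one-to-one", {
  truth <- c(100L, 500L, 900L)
  same <- match_peaks(truth, truth, fs = 250)
  expect_equal(same$TP, 3L)
  expect_equal(same$FP, 0L)
  expect_equal(same$FN, 0L)
  # 10 ms offset at 250 Hz (2.5 samples) is inside the 31.25 ms tolerance
  r <- match_peaks(c(102L), c(100L), fs = 250)
  expect_equal(r$TP, 1L)
  # two predictions near one truth: only one can match
  r2 <- match_peaks(c(98L, 103L), c(100L), fs = 250)
  expect_equal(r2$TP, 1L)
  expect_equal(r2$FP, 1L)
  expect_equal(unname(r2$matches[1, "predicted"]), 98L)  # tie to nearest
  expect_error(match_peaks(c(5L, 3L), truth), "sorted")
  # counts are conserved for arbitrary fuzzed inputs
  set.seed(8)
  for (i in 1:50) {
    p <- sort(sample.int(2000, sample(0:8, 1)))
    t <- sort(sample.int(2000, sample(1:8, 1)))
    res <- match_peaks(p, t, fs = 250)
    expect_equal(res$TP + res$FP, length(p))
    expect_equal(res$TP + res$FN, length(t))
    if (!is.null(res$matches))
      expect_true(all(abs(res$matches[, 1] - res$matches[, 2]) <=
                        0.03125 * 250))
  }
})

test_that("greedy matching is optimal for physiologically spaced peaks", {
  set.seed(9)
  tol <- 0.03125 * 250
  for (i in 1:200) {
    nt <- sample(2:8, 1)
    t <- random_peak_train(nt, min_gap = ceiling(2 * tol) + 1, spread = 60)
    keep <- runif(nt) < 0.85
    p <- t[keep] + sample(-9:9, sum(keep), replace = TRUE)
    p <- c(p, sample.int(max(t) + 50, sample(0:3, 1)))    # spurious extras
    p <- sort(p[p >= 1])
    res <- match_peaks(p, t, fs = 250)
    expect_equal(res$TP, oracle_match_count(p, t, tol))
  }
})

test_that("detection scores include the harmonic F1 and the count-ratio variant", {
  s <- detection_scores(list(TP = 100, FP = 0, FN = 0))
  expect_equal(s$se_pct, 100)
  expect_equal(s$ppv_pct, 100)
  expect_equal(s$f1_pct, 100)
  s2 <- detection_scores(list(TP = 90, FP = 10, FN = 10))
  expect_equal(s2$se_pct, 90)
  expect_equal(s2$ppv_pct, 90)
  expect_equal(s2$f1_pct, 90)
  expect_equal(s2$f1_jaccard_pct, 100 * 90 / 110, tolerance = 1e-9)
  expect_error(detection_scores(list(TP = 0, FP = 0, FN = 0)), "undefined")
  # F1 lies between SE and PPV; count-ratio variant never exceeds it
  set.seed(10)
  for (i in 1:100) {
    cnt <- list(TP = sample(1:50, 1), FP = sample(0:20, 1),
                FN = sample(0:20, 1))
    sc <- detection_scores(cnt)
    expect_gte(sc$f1_pct, min(sc$se_pct, sc$ppv_pct) - 1e-9)
    expect_lte(sc$f1_pct, max(sc$se_pct, sc$ppv_pct) + 1e-9)
    expect_lte(sc$f1_jaccard_pct, sc$f1_pct + 1e-9)
  }
})

test_that("record evaluation reports only the metrics its inputs support", {
  m <- r2wnet_model(r2wnet_config(width_multiplier = 1 / 16), seed = 1)
  rec <- quick_record(30, seed = 55)
  rep <- evaluate_record(rec, m)
  expect_true(is.finite(rep$mse))
  expect_true(is.finite(rep$snr_in_db))
  expect_equal(rep$n_true_beats, length(rec$rpeaks_fetal))
  # annotations only: signal metrics absent (NA), detection present
  rec_ann <- rec
  keep <- rec$channel_roles == "abdominal_mixture"
  rec_ann$signals <- rec$signals[, keep, drop = FALSE]
  rec_ann$channel_roles <- rec$channel_roles[keep]
  rep2 <- evaluate_record(rec_ann, m)
  expect_true(is.na(rep2$mse))
  expect_false(is.na(rep2$n_true_beats))
  # neither truth nor annotations: error
  rec_none <- rec_ann
  rec_none$rpeaks_fetal <- integer()
  expect_error(evaluate_record(rec_none, m), "neither")
  # the mixture-as-prediction reference equals the directly computed SNR
  pp <- preprocess_record(rec)
  direct <- signal_metrics(record_channel(pp$record, "fetal_truth"),
                           record_channel(pp$record, "abdominal_mixture"))
  expect_equal(rep$snr_in_db, direct$snr_db, tolerance = 1e-9)
})

test_that("aggregation matches per-record averaging and pooled counting", {
  mk <- function(mse, snr, se, ppv, ntb) {
    structure(list(mse = mse, mae = mse / 2, snr_db = snr, snr_in_db = 0,
                   se_pct = se, ppv_pct = ppv,
                   f1_pct = 2 * se * ppv / (se + ppv),
                   f1_jaccard_pct = NA_real_, n_samples = 1000L,
                   n_true_beats = ntb, record_id = "x"),
              class = "metrics_report")
  }
  reps <- list(mk(0.02, 9, 99, 98, 100), mk(0.03, 7, 97, 99, 120))
  agg <- aggregate_reports(reps)
  expect_equal(agg$mse, 0.025)
  expect_equal(agg$snr_db, 8)
  expect_equal(agg$se_pct, 98)
  # single report: mean equals the report, spread 0
  one <- aggregate_reports(reps[1])
  expect_equal(one$mse, 0.02)
  expect_equal(one$mse_sd, 0)
  # pooled mode sums the counts before scoring
  pooled <- aggregate_reports(reps, mode = "pooled")
  tp <- 0.99 * 100 + 0.97 * 120
  fn <- 100 + 120 - tp
  fp <- 0.99 * 100 / 0.98 - 0.99 * 100 + 0.97 * 120 / 0.99 - 0.97 * 120
  expect_equal(pooled$se_pct, 100 * tp / (tp + fn), tolerance = 1e-9)
  expect_equal(pooled$ppv_pct, 100 * tp / (tp + fp), tolerance = 1e-6)
  expect_error(aggregate_reports(list()), "empty")
})
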
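# Shared fixtures. The desk-scale training runs are expensive, so they are
# computed lazily once per test session and reused by every test that
# needs a trained model.

quick_record <- function(duration_s = 30, seed = 1, scenario = "C0",
                         noise = 6, ...) {
  simulate_record(scenario_spec(scenario, noise_snr_db = noise,
                                duration_s = duration_s, seed = seed, ...))
}

# Study conditions for the desk-scale end-to-end run: scenario C0 at 6 dB
# noise, seven 120 s training records (one held out for validation by the
# record-level split) and five 60 s evaluation records; width-1/8 network,
# desk training preset.
desk_train_records <- function(seed) {
  lapply(1:7, function(i) quick_record(120, seed * 1000 + i))
}

desk_eval_records <- function(seed) {
  lapply(1:5, function(i) quick_record(60, seed * 1000 + 900 + i))
}

.desk_cache <- new.env(parent = emptyenv())

desk_run <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.desk_cache[[key]])) return(.desk_cache[[key]])
  recs <- desk_train_records(seed)
  cfg <- r2wnet_config(width_multiplier = 1 / 8)
  tc <- train_config(preset = "desk", seed = seed)
  untrained <- r2wnet_model(cfg, seed = seed)
  fit <- train_r2wnet(untrained, recs, tc)
  ev <- desk_eval_records(seed)
  reports <- lapply(ev, evaluate_record, model = fit$model)
  # validation loss of the untrained weights on the held-out records, for
  # the improvement invariant
  data <- r2wnet:::build_training_windows(ev)
  idx <- seq_along(data$x)
  val0 <- r2wnet:::eval_loss_on(untrained$params, cfg, data, idx, tc)
  val1 <- r2wnet:::eval_loss_on(fit$model$params, cfg, data, idx, tc)
  out <- list(fit = fit, history = fit$history, reports = reports,
              untrained_val = val0, trained_val = val1)
  .desk_cache[[key]] <- out
  out
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", actual, expected, tol))
}
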
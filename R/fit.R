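#' Fit a W-shaped fetal-ECG separator
#'
#' The main modelling entry point. Takes abdominal records with ground
#' truth (synthetic, from [simulate_record()]/[make_dataset()], or any
#' records carrying `fetal_truth` and `maternal_truth` channels), builds
#' the dual attention R2U-Net, and trains both branches jointly. Returns a
#' classed fit with the usual methods: [predict.r2wnet()] extracts fetal
#' and maternal components from new records, plus `print`, `summary`,
#' `coef`, `plot` and `residuals`.
#'
#' @param records list of [ecg_record()] objects, or a manifest path/dir
#'   from [make_dataset()].
#' @param config an [r2wnet_config()]; the default desk-scale width is
#'   1/8 of the reference network.
#' @param training a [train_config()].
#' @param seed integer seed for weight initialisation (shuffling uses
#'   `training$seed`).
#' @return an object of class `r2wnet`: list with `params`, `config`,
#'   `training`, `history`, `seed`, `n_records`.
#' @seealso [train_r2wnet()] for the bare training loop,
#'   [evaluate_record()] for scoring.
#' @examples
#' \donttest{
#' specs <- lapply(1:3, function(i)
#'   scenario_spec("C0", noise_snr_db = 6, duration_s = 30, seed = i))
#' recs <- lapply(specs, simulate_record)
#' fit <- r2wnet(recs, config = r2wnet_config(width_multiplier = 1 / 16),
#'               training = train_config(epochs = 1))
#' print(fit)
#' }
#' @export
r2wnet <- function(records, config = r2wnet_config(width_multiplier = 1 / 8),
                   training = train_config(), seed = 1L) {
  if (is.character(records)) records <- load_dataset(records)
  model <- r2wnet_model(config, seed = seed)
  res <- train_r2wnet(model, records, training)
  structure(list(params = res$model$params, config = config,
                 training = training, history = res$history,
                 seed = as.integer(seed), n_records = length(records)),
            class = c("r2wnet", "r2wnet_model"))
}

#' Extract fetal and maternal components from a record
#'
#' Inference chain for one record: band-pass, resample to 250 Hz, window
#' and Z-score the abdominal channel, run every window through the
#' network, and stitch the outputs back to record scale (overlap-discard;
#' the fetal reconstruction is denormalised by the window scale only, the
#' maternal one by scale and mean). The returned record carries the
#' conditioned input channels plus `fecg_pred` and `mecg_pred`.
#'
#' @param record an [ecg_record()] with an `abdominal_mixture` channel.
#' @param model an `r2wnet` fit or `r2wnet_model`.
#' @return an [ecg_record()] at 250 Hz with prediction channels appended.
#' @export
extract_record <- function(record, model) {
  pp <- preprocess_record(record)
  segs_f <- vector("list", length(pp$input$segments))
  segs_m <- segs_f
  for (i in seq_along(pp$input$segments)) {
    out <- forward_segment(pp$input$segments[[i]], model)
    segs_f[[i]] <- out$fecg
    segs_m[[i]] <- out$mecg
  }
  fhat <- stitch_segments(pp$input, segs_f, denorm = "scale")
  mhat <- stitch_segments(pp$input, segs_m, denorm = "affine")
  rec <- pp$record
  rec$signals <- cbind(rec$signals, fhat, mhat)
  rec$channel_roles <- c(rec$channel_roles, "fecg_pred", "mecg_pred")
  validate_record(rec)
  rec
}

#' Predict method: component extraction
#'
#' @param object an `r2wnet` fit.
#' @param newdata an [ecg_record()] (or list of records).
#' @param type `"record"` returns the record with prediction channels;
#'   `"fecg"`/`"mecg"` return just that reconstructed channel.
#' @param ... unused.
#' @return see `type`; a list when `newdata` is a list.
#' @export
predict.r2wnet <- function(object, newdata,
                           type = c("record", "fecg", "mecg"), ...) {
  type <- match.arg(type)
  one <- function(rec) {
    ext <- extract_record(rec, object)
    switch(type, record = ext, fecg = record_channel(ext, "fecg_pred"),
           mecg = record_channel(ext, "mecg_pred"))
  }
  if (inherits(newdata, "ecg_record")) one(newdata) else lapply(newdata, one)
}

#' Residuals of the fetal reconstruction
#'
#' @param object an `r2wnet` fit.
#' @param record an [ecg_record()] with a `fetal_truth` channel.
#' @param ... unused.
#' @return numeric vector `fetal_truth - fecg_pred` (in the conditioned
#'   250 Hz domain).
#' @export
residuals.r2wnet <- function(object, record, ...) {
  ext <- extract_record(record, object)
  record_channel(ext, "fetal_truth") - record_channel(ext, "fecg_pred")
}

#' @export
coef.r2wnet <- function(object, ...) object$params

#' @export
print.r2wnet <- function(x, ...) {
  cat("<r2wnet> fitted W-shaped fetal/maternal ECG separator\n")
  print(x$config)
  h <- x$history
  cat(sprintf("  %s parameters, trained on %d record(s), %d epoch(s)\n",
              format(count_parameters(x), big.mark = ","), x$n_records,
              nrow(h)))
  cat(sprintf("  final train loss %.5f, best validation loss %.5f (epoch %d)\n",
              h$train_loss[nrow(h)],
              suppressWarnings(min(h$val_loss, na.rm = TRUE)),
              attr(h, "best_epoch")))
  invisible(x)
}

#' @export
summary.r2wnet <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history)
  invisible(object)
}

#' Plot a fit: training curves or an extraction overlay
#'
#' With only the fit, plots training/validation loss per epoch. With a
#' record, overlays the fetal reconstruction on the fetal truth (first
#' `window_s` seconds).
#'
#' @param x an `r2wnet` fit.
#' @param record optional [ecg_record()] to extract and display.
#' @param window_s seconds of signal to show.
#' @param ... passed to [graphics::plot()].
#' @export
plot.r2wnet <- function(x, record = NULL, window_s = 5, ...) {
  if (is.null(record)) {
    h <- x$history
    graphics::plot(h$epoch, h$train_loss, type = "b", pch = 16,
                   xlab = "epoch", ylab = "loss", ...)
    if (any(is.finite(h$val_loss))) {
      graphics::lines(h$epoch, h$val_loss, type = "b", pch = 1, lty = 2)
      graphics::legend("topright", c("train", "validation"),
                       pch = c(16, 1), lty = c(1, 2), bty = "n")
    }
  } else {
    ext <- extract_record(record, x)
    n <- min(record_length(ext), round(window_s * ext$fs))
    t <- (seq_len(n) - 1) / ext$fs
    ft <- record_channel(ext, "fetal_truth", required = FALSE)
    fh <- record_channel(ext, "fecg_pred")
    graphics::plot(t, fh[seq_len(n)], type = "l", col = "firebrick",
                   xlab = "time (s)", ylab = "amplitude (mV)", ...)
    if (!is.null(ft)) {
      graphics::lines(t, ft[seq_len(n)], col = "grey40")
      graphics::legend("topright", c("fetal truth", "extracted"),
                       col = c("grey40", "firebrick"), lty = 1, bty = "n")
    }
  }
  invisible(x)
}

#' Save / load a fitted separator
#'
#' The checkpoint is a directory holding the weights (`weights.rds`) and a
#' JSON config sidecar (`config.json`) so the architecture is
#' reconstructible without relying on code defaults.
#'
#' @param object an `r2wnet` fit or `r2wnet_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_r2wnet <- function(object, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create checkpoint directory: ", dir)
  saveRDS(object$params, file.path(dir, "weights.rds"))
  cfg <- unclass(object$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(object$history))
    utils::write.table(object$history, file.path(dir, "history.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname save_r2wnet
#' @param dir checkpoint directory written by [save_r2wnet()].
#' @export
load_r2wnet <- function(dir) {
  wf <- file.path(dir, "weights.rds"); cf <- file.path(dir, "config.json")
  if (!file.exists(wf) || !file.exists(cf))
    stop("not a checkpoint directory (weights.rds/config.json missing): ",
         dir)
  cfg <- jsonlite::read_json(cf, simplifyVector = TRUE)
  config <- r2wnet_config(depth = cfg$depth, channels = cfg$channels,
                          kernel_maternal = cfg$kernel_maternal,
                          kernel_fetal = cfg$kernel_fetal,
                          recurrence_T = cfg$recurrence_T,
                          fusion_levels = cfg$fusion_levels,
                          fuse_feedforward = cfg$fuse_feedforward,
                          activation = cfg$activation,
                          block_type = cfg$block_type,
                          attention = cfg$attention,
                          input_length = cfg$input_length)
  params <- readRDS(wf)
  model <- r2wnet_model(config, seed = 1L)
  if (!setequal(names(params), names(model$params)) ||
      !all(vapply(names(params), function(nm)
        length(params[[nm]]) == length(model$params[[nm]]), logical(1))))
    stop("checkpoint weights do not match the architecture in config.json",
         " (parameter names or shapes differ)")
  model$params <- params
  hf <- file.path(dir, "history.tsv")
  if (file.exists(hf))
    model$history <- utils::read.table(hf, header = TRUE, sep = "\t")
  model
}
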
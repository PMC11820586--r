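#' Signal-level extraction quality
#'
#' Compares an extracted channel against its ground truth:
#' `MSE = mean((y - yhat)^2)`, `MAE = mean(|y - yhat|)`,
#' `SNR = 10*log10(sum(y^2) / sum((y - yhat)^2))` in dB. A perfect
#' reconstruction yields `SNR = Inf`.
#'
#' @param y_true numeric vector, true component amplitudes.
#' @param y_pred numeric vector of the same length, extracted amplitudes.
#' @return list with `mse`, `mae`, `snr_db`.
#' @export
signal_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (all(y_true == 0)) stop("SNR undefined for an all-zero true signal")
  r <- y_true - y_pred
  den <- sum(r^2)
  list(mse = mean(r^2), mae = mean(abs(r)),
       snr_db = if (den == 0) Inf else 10 * log10(sum(y_true^2) / den))
}

#' Pan-Tompkins QRS detection
#'
#' Classic QRS detector: band-pass filtering, differentiation, squaring,
#' moving-window integration, then adaptive dual-threshold peak search with
#' a refractory period and a search-back pass for missed beats. The
#' `"fetal"` profile uses a higher pass band (8-25 Hz), a shorter
#' integration window (80 ms) and a shorter refractory period (200 ms) to
#' follow the narrower fetal QRS at rates up to 240 bpm; the `"maternal"`
#' profile uses 5-15 Hz, 150 ms and 250 ms. Detected positions are refined
#' to the nearest extremum of the band-passed signal.
#'
#' @param x numeric vector, one channel.
#' @param fs sampling rate in Hz (>= 250).
#' @param profile `"fetal"` or `"maternal"`.
#' @return integer vector of 1-based R-peak sample indices (empty when no
#'   peaks are found).
#' @export
pan_tompkins <- function(x, fs = 250, profile = c("fetal", "maternal")) {
  profile <- match.arg(profile)
  if (fs < 250) stop("fs must be >= 250 Hz")
  if (length(x) < 2 * fs) stop("signal must be at least 2 s long")
  if (all(x == 0)) return(integer())
  band <- if (profile == "fetal") c(8, 25) else c(5, 15)
  win_s <- if (profile == "fetal") 0.08 else 0.15
  refr_s <- if (profile == "fetal") 0.20 else 0.25
  bf <- signal::butter(2, band / (fs / 2), "pass")
  xf <- as.numeric(signal::filtfilt(bf, as.numeric(x)))
  dx <- c(0, diff(xf)) * fs
  sq <- dx^2
  w <- max(3L, round(win_s * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  n <- length(integ)
  refr <- round(refr_s * fs)

  # candidate peaks of the integrated signal
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  if (!length(cand)) return(integer())

  # adaptive dual thresholds (running signal / noise peak estimates)
  spki <- stats::quantile(integ[cand], 0.75, names = FALSE)
  npki <- stats::quantile(integ[cand], 0.25, names = FALSE)
  thr <- function() npki + 0.25 * (spki - npki)
  peaks <- integer(); last <- -Inf; accepted_amp <- numeric()
  for (p in cand) {
    a <- integ[p]
    if (p - last < refr) {
      if (length(peaks) && a > 1.5 * integ[peaks[length(peaks)]] &&
          p - (if (length(peaks) > 1) peaks[length(peaks) - 1] else -Inf) >=
          refr) {
        # replace the previous (weaker) detection inside the refractory span
        peaks[length(peaks)] <- p
        last <- p
        spki <- 0.125 * a + 0.875 * spki
      } else npki <- 0.125 * a + 0.875 * npki
      next
    }
    if (a >= thr()) {
      peaks <- c(peaks, p); last <- p
      spki <- 0.125 * a + 0.875 * spki
      accepted_amp <- c(accepted_amp, a)
    } else npki <- 0.125 * a + 0.875 * npki
  }
  # search-back: re-scan long gaps with half the threshold
  if (length(peaks) > 2) {
    rr <- diff(peaks)
    med_rr <- stats::median(rr)
    extra <- integer()
    for (i in which(rr > 1.66 * med_rr)) {
      seg <- cand[cand > peaks[i] + refr & cand < peaks[i + 1] - refr]
      seg <- seg[integ[seg] >= 0.5 * thr()]
      if (length(seg)) extra <- c(extra, seg[which.max(integ[seg])])
    }
    peaks <- sort(unique(c(peaks, extra)))
  }
  # refine to the nearest extremum of the band-passed signal; the
  # integrator is centred (sides = 2) so the offset is small
  half <- round(w / 2)
  ref <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo + which.max(abs(xf[lo:hi])) - 1L
  }, numeric(1))
  sort(unique(as.integer(ref)))
}

#' Match predicted to true R peaks under a timing tolerance
#'
#' Greedy nearest one-to-one matching: candidate pairs within the tolerance
#' are accepted in order of increasing time difference (ties broken toward
#' the earlier predicted peak); each true and each predicted peak is
#' matched at most once. Unmatched predictions are false positives,
#' unmatched truths false negatives. For physiological peak trains (true
#' peaks farther apart than twice the tolerance) this greedy matching
#' attains the maximum possible number of matches.
#'
#' @param predicted,truth integer sample indices, each sorted ascending.
#' @param fs sampling rate in Hz.
#' @param tolerance_s matching tolerance in seconds (default 31.25 ms).
#' @return a `detection_result`: list with `TP`, `FP`, `FN`, `matches`
#'   (two-column matrix of predicted/true indices), `tolerance_s`.
#' @export
match_peaks <- function(predicted, truth, fs = 250, tolerance_s = 0.03125) {
  if (is.unsorted(predicted, strictly = FALSE) ||
      is.unsorted(truth, strictly = FALSE))
    stop("peak index lists must be sorted ascending")
  tol <- tolerance_s * fs
  np <- length(predicted); nt <- length(truth)
  pairs <- NULL
  if (np && nt) {
    d <- abs(outer(predicted, truth, "-"))
    ok <- which(d <= tol, arr.ind = TRUE)
    if (nrow(ok)) {
      dd <- d[ok]
      ord <- order(dd, predicted[ok[, 1]])
      ok <- ok[ord, , drop = FALSE]
      usedp <- logical(np); usedt <- logical(nt)
      keep <- logical(nrow(ok))
      for (i in seq_len(nrow(ok))) {
        p <- ok[i, 1]; t <- ok[i, 2]
        if (!usedp[p] && !usedt[t]) {
          usedp[p] <- TRUE; usedt[t] <- TRUE; keep[i] <- TRUE
        }
      }
      ok <- ok[keep, , drop = FALSE]
      if (nrow(ok))
        pairs <- cbind(predicted = predicted[ok[, 1]], truth = truth[ok[, 2]])
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  structure(list(TP = tp, FP = np - tp, FN = nt - tp,
                 matches = pairs, tolerance_s = tolerance_s),
            class = "detection_result")
}

#' Beat-detection scores
#'
#' Sensitivity `SE = TP/(TP+FN)`, positive predictive value
#' `PPV = TP/(TP+FP)`, and their harmonic mean
#' `F1 = 2*SE*PPV/(SE+PPV)`, all in percent. The count-ratio variant
#' `TP/(TP+FP+FN)` (the Jaccard index of the two peak sets) is also
#' returned as `f1_jaccard_pct`; it is always less than or equal to the
#' harmonic-mean F1.
#'
#' @param result a `detection_result` from [match_peaks()], or a list with
#'   `TP`, `FP`, `FN` counts.
#' @return list with `se_pct`, `ppv_pct`, `f1_pct`, `f1_jaccard_pct`.
#' @export
detection_scores <- function(result) {
  tp <- result$TP; fp <- result$FP; fn <- result$FN
  if (tp + fn == 0 || tp + fp == 0)
    stop("scores undefined: need at least one true and one predicted peak")
  se <- 100 * tp / (tp + fn)
  ppv <- 100 * tp / (tp + fp)
  f1 <- if (se + ppv == 0) 0 else 2 * se * ppv / (se + ppv)
  list(se_pct = se, ppv_pct = ppv, f1_pct = f1,
       f1_jaccard_pct = 100 * tp / (tp + fp + fn))
}

#' Evaluate a trained separator on one record
#'
#' Runs the full inference chain — preprocessing, per-window forward pass,
#' overlap-discard stitching — then scores the fetal reconstruction
#' against the (identically preprocessed) fetal truth channel with
#' [signal_metrics()], and fetal QRS detection with [pan_tompkins()] +
#' [match_peaks()] + [detection_scores()] against the R-peak annotations.
#' Metrics whose reference is missing are reported as `NA`, never as
#' zero. As a reference point, `snr_in_db` scores the unprocessed mixture
#' against the same truth — the improvement achieved by the network is
#' `snr_db - snr_in_db`.
#'
#' @param record an [ecg_record()] with an abdominal channel plus fetal
#'   truth and/or fetal R-peak annotations.
#' @param model an `r2wnet_model` or `r2wnet` fit.
#' @param tolerance_s QRS matching tolerance in seconds.
#' @return a `metrics_report`: list with `mse`, `mae`, `snr_db`,
#'   `snr_in_db`, `se_pct`, `ppv_pct`, `f1_pct`, `f1_jaccard_pct`,
#'   `n_samples`, `n_true_beats`, `record_id`.
#' @export
evaluate_record <- function(record, model, tolerance_s = 0.03125) {
  validate_record(record)
  has_truth <- "fetal_truth" %in% record$channel_roles
  has_ann <- length(record$rpeaks_fetal) > 0
  if (!has_truth && !has_ann)
    stop("record has neither a fetal_truth channel nor fetal annotations")
  ext <- extract_record(record, model)
  fhat <- record_channel(ext, "fecg_pred")
  rep <- list(mse = NA_real_, mae = NA_real_, snr_db = NA_real_,
              snr_in_db = NA_real_, se_pct = NA_real_, ppv_pct = NA_real_,
              f1_pct = NA_real_, f1_jaccard_pct = NA_real_,
              n_samples = length(fhat), n_true_beats = NA_integer_,
              record_id = record$meta$record_id %||% NA_character_)
  if (has_truth) {
    ft <- record_channel(ext, "fetal_truth")
    sm <- signal_metrics(ft, fhat)
    rep$mse <- sm$mse; rep$mae <- sm$mae; rep$snr_db <- sm$snr_db
    mix <- record_channel(ext, "abdominal_mixture")
    rep$snr_in_db <- signal_metrics(ft, mix)$snr_db
  }
  if (has_ann) {
    truth_pk <- ext$rpeaks_fetal
    rep$n_true_beats <- length(truth_pk)
    pred_pk <- pan_tompkins(fhat, fs = ext$fs, profile = "fetal")
    if (length(pred_pk) && length(truth_pk)) {
      ds <- detection_scores(match_peaks(pred_pk, truth_pk, fs = ext$fs,
                                         tolerance_s = tolerance_s))
      rep[names(ds)] <- ds
    } else {
      rep$se_pct <- 0; rep$ppv_pct <- NA_real_
      rep$f1_pct <- 0; rep$f1_jaccard_pct <- 0
    }
  }
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", if (!is.na(x$record_id)) x$record_id, "\n")
  if (!is.na(x$mse))
    cat(sprintf("  MSE %.4f  MAE %.4f  SNR %.2f dB (mixture %.2f dB)\n",
                x$mse, x$mae, x$snr_db, x$snr_in_db))
  if (!is.na(x$f1_pct))
    cat(sprintf("  FQRS: SE %.2f%%  PPV %.2f%%  F1 %.2f%%  (%d true beats)\n",
                x$se_pct, x$ppv_pct, x$f1_pct, x$n_true_beats))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate per-record reports
#'
#' `mode = "mean_per_record"` averages every metric across records and
#' reports its spread (standard deviation with the population `n`
#' denominator, the convention used when tables print `mean +/- std` over
#' a fixed record set). `mode = "pooled"` sums TP/FP/FN over records
#' before scoring the detection metrics (signal metrics are sample-count
#' weighted means).
#'
#' @param reports list of `metrics_report` objects (nonempty).
#' @param mode `"mean_per_record"` or `"pooled"`.
#' @return named list of aggregated metrics; per-metric spreads are in
#'   `<name>_sd` for the mean mode.
#' @export
aggregate_reports <- function(reports, mode = c("mean_per_record", "pooled")) {
  mode <- match.arg(mode)
  if (!length(reports)) stop("empty report list")
  get <- function(nm) vapply(reports, function(r)
    as.numeric(r[[nm]] %||% NA_real_), numeric(1))
  metrics <- c("mse", "mae", "snr_db", "snr_in_db", "se_pct", "ppv_pct",
               "f1_pct", "f1_jaccard_pct")
  out <- list(n_records = length(reports), mode = mode)
  if (mode == "mean_per_record") {
    for (nm in metrics) {
      v <- get(nm); v <- v[is.finite(v)]
      out[[nm]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(nm, "_sd")]] <- if (length(v))
        sqrt(mean((v - mean(v))^2)) else NA_real_
    }
  } else {
    ns <- get("n_samples")
    for (nm in c("mse", "mae")) {
      v <- get(nm)
      keep <- is.finite(v)
      out[[nm]] <- if (any(keep))
        sum(v[keep] * ns[keep]) / sum(ns[keep]) else NA_real_
    }
    v <- get("snr_db"); v <- v[is.finite(v)]
    out$snr_db <- if (length(v)) mean(v) else NA_real_
    tp <- fp <- fn <- 0
    any_det <- FALSE
    for (r in reports) {
      if (is.na(r$f1_pct)) next
      any_det <- TRUE
      se <- r$se_pct / 100; ppv <- r$ppv_pct / 100
      ntb <- r$n_true_beats
      tpi <- se * ntb
      tp <- tp + tpi; fn <- fn + ntb - tpi
      fp <- fp + if (is.finite(ppv) && ppv > 0) tpi / ppv - tpi else 0
    }
    if (any_det) {
      sc <- detection_scores(list(TP = tp, FP = fp, FN = fn))
      out[names(sc)] <- sc
    }
  }
  out
}

#' Write per-record reports and a summary row as a delimited table
#'
#' @param reports list of `metrics_report` objects.
#' @param file output path (tab-separated text).
#' @param mode aggregation mode for the summary row.
#' @return the table, invisibly.
#' @export
write_report_table <- function(reports, file,
                               mode = "mean_per_record") {
  cols <- c("record_id", "mse", "mae", "snr_db", "snr_in_db", "se_pct",
            "ppv_pct", "f1_pct", "n_true_beats")
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(lapply(stats::setNames(cols, cols), function(nm)
      r[[nm]] %||% NA), stringsAsFactors = FALSE)))
  agg <- aggregate_reports(reports, mode)
  sumrow <- data.frame(record_id = "summary", mse = agg$mse, mae = agg$mae,
                       snr_db = agg$snr_db, snr_in_db = agg$snr_in_db,
                       se_pct = agg$se_pct, ppv_pct = agg$ppv_pct,
                       f1_pct = agg$f1_pct, n_true_beats = NA)
  tab <- rbind(tab, sumrow)
  utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tab)
}
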
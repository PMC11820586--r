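#' Zero-phase 3-100 Hz band-pass filter
#'
#' Conditions a raw abdominal channel by removing baseline drift below 3 Hz
#' (including DC) and wideband noise above 100 Hz. The filter is a
#' Butterworth high-pass (order 4, corner near 3 Hz) cascaded with a
#' Butterworth low-pass (order 6, corner near 100 Hz), each applied
#' forward-backward (`filtfilt`) so the phase response is zero and R-peak
#' timing is preserved. The analogue corners are pre-warped so that the
#' *combined* two-pass magnitude is -3 dB at 3 and 100 Hz; the passband is
#' flat within about 1 dB between 5 and 90 Hz. 50 Hz powerline interference
#' lies inside the passband and is deliberately left in: removing it is the
#' separation network's job.
#'
#' @param x numeric vector, one channel.
#' @param fs sampling rate in Hz; must exceed 200 Hz so the 100 Hz band is
#'   representable — filter before downsampling.
#' @param low,high corner frequencies in Hz.
#' @return filtered channel, same length.
#' @export
bandpass_ecg <- function(x, fs, low = 3, high = 100) {
  if (fs <= 200)
    stop("fs must exceed 200 Hz: band-pass filter before downsampling")
  # two filtfilt passes double the attenuation; shift the design corners so
  # the combined response is -3 dB at `low` and `high`
  adj <- function(n) (sqrt(2) - 1)^(1 / (2 * n))
  hp <- signal::butter(4, (low * adj(4)) / (fs / 2), type = "high")
  lp <- signal::butter(6, min((high / adj(6)) / (fs / 2), 0.98), type = "low")
  y <- signal::filtfilt(hp, as.numeric(x))
  as.numeric(signal::filtfilt(lp, y))
}

#' Band-pass filter every channel of a record
#'
#' Applies [bandpass_ecg()] to all channels (truth channels included, so
#' extraction targets live in the same band as the conditioned mixture).
#'
#' @param rec an [ecg_record()].
#' @param low,high corner frequencies in Hz.
#' @return the filtered [ecg_record()].
#' @export
bandpass_record <- function(rec, low = 3, high = 100) {
  validate_record(rec)
  out <- rec
  out$signals <- apply(rec$signals, 2, bandpass_ecg, fs = rec$fs,
                       low = low, high = high)
  if (!is.matrix(out$signals)) out$signals <- matrix(out$signals, ncol = 1)
  out
}

#' Resample a record to a target rate
#'
#' Zero-phase rational resampling of every channel: when downsampling, a
#' zero-phase Butterworth anti-alias filter (order 6, cut-off at 90% of
#' the new Nyquist, applied forward-backward) precedes the rate change;
#' integer decimation is exact sample picking and non-integer ratios use
#' cubic-spline interpolation on the filtered signal. Because every step
#' is zero-phase, R-peak timing is preserved; annotation indices are
#' rescaled by `fs_target/fs` and rounded to the nearest sample. Identity
#' when the record is already at the target rate.
#'
#' @param rec an [ecg_record()].
#' @param fs_target target sampling rate in Hz (default 250).
#' @return the resampled [ecg_record()] with `fs = fs_target`.
#' @export
resample_record <- function(rec, fs_target = 250) {
  validate_record(rec)
  if (abs(rec$fs - fs_target) < 1e-9) return(rec)
  n_new <- floor((nrow(rec$signals) - 1) * fs_target / rec$fs) + 1L
  sig <- apply(rec$signals, 2, resample_channel, fs_from = rec$fs,
               fs_to = fs_target, n_new = n_new)
  if (!is.matrix(sig)) sig <- matrix(sig, ncol = 1)
  remap <- function(pk) {
    if (!length(pk)) return(integer())
    idx <- as.integer(round((pk - 1L) * fs_target / rec$fs) + 1L)
    idx[idx >= 1L & idx <= n_new]
  }
  out <- rec
  out$signals <- sig
  out$fs <- fs_target
  out$rpeaks_fetal <- remap(rec$rpeaks_fetal)
  out$rpeaks_maternal <- remap(rec$rpeaks_maternal)
  if (!is.null(out$meta$noise))
    out$meta$noise <- resample_channel(out$meta$noise, rec$fs, fs_target,
                                       n_new)
  validate_record(out)
  out
}

resample_channel <- function(x, fs_from, fs_to, n_new) {
  if (fs_to < fs_from) {
    lp <- signal::butter(6, 0.9 * fs_to / fs_from, type = "low")
    x <- as.numeric(signal::filtfilt(lp, as.numeric(x)))
    ratio <- fs_from / fs_to
    if (abs(ratio - round(ratio)) < 1e-9)   # exact integer decimation
      return(x[seq(1L, by = round(ratio), length.out = n_new)])
  }
  t_old <- (seq_along(x) - 1) / fs_from
  t_new <- (seq_len(n_new) - 1) / fs_to
  stats::spline(t_old, x, xout = t_new, method = "fmm")$y
}

#' Cut a channel into overlapped fixed-length windows
#'
#' Splits one channel into windows of `width` samples with `margin`
#' untrusted samples at both ends, i.e. a hop of `width - 2*margin`
#' (1024 - 48 = 976 by default). The final window is anchored at
#' `length - width + 1` so the tail is always covered, possibly with a
#' larger overlap.
#'
#' @param x numeric vector (one channel, nominally at 250 Hz).
#' @param fs sampling rate stored with the set.
#' @param width window length in samples.
#' @param margin overlap at each window end, in samples.
#' @return a `segment_set`: list with `segments` (list of numeric vectors),
#'   `offsets` (1-based start indices), `width`, `margin`, `fs`,
#'   `source_length`, and a `norm_state` slot filled by
#'   [zscore_segments()].
#' @export
segment_signal <- function(x, fs = 250, width = 1024L, margin = 24L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < width)
    stop("signal shorter than one window (", n, " < ", width,
         "); zero-pad the record first if segmentation is required")
  hop <- width - 2L * margin
  offsets <- seq(1L, n - width + 1L, by = hop)
  last <- offsets[length(offsets)]
  if (last + width - 1L < n) {
    anchor <- n - width + 1L
    # re-anchor the final window at the tail; keep the previous window when
    # it is still needed for coverage
    if (length(offsets) >= 2L &&
        anchor <= offsets[length(offsets) - 1L] + width)
      offsets[length(offsets)] <- anchor
    else offsets <- c(offsets, anchor)
  }
  segments <- lapply(offsets, function(o) x[o:(o + width - 1L)])
  structure(list(segments = segments, offsets = as.integer(offsets),
                 width = as.integer(width), margin = as.integer(margin),
                 fs = fs, source_length = as.integer(n), norm_state = NULL),
            class = "segment_set")
}

#' Per-segment Z-score normalisation
#'
#' Standardises every window independently to mean 0 and standard deviation
#' 1, recording the per-window `(mean, sd)` in `norm_state` so the
#' transform can be inverted by [stitch_segments()]. The standard deviation
#' is floored at `eps` to guard flat windows (which become all-zero).
#'
#' @param set a `segment_set` from [segment_signal()].
#' @param eps standard-deviation floor.
#' @return the normalised `segment_set` with `norm_state` filled.
#' @export
zscore_segments <- function(set, eps = 1e-8) {
  stopifnot(inherits(set, "segment_set"))
  mu <- vapply(set$segments, mean, numeric(1))
  sg <- pmax(vapply(set$segments, stats::sd, numeric(1)), eps)
  sg[!is.finite(sg)] <- eps
  set$segments <- lapply(seq_along(set$segments), function(i)
    (set$segments[[i]] - mu[i]) / sg[i])
  set$norm_state <- cbind(mean = mu, sd = sg)
  set
}

#' Reassemble transformed windows into one channel
#'
#' Inverse of [segment_signal()]/[zscore_segments()] for model outputs:
#' each transformed window is first denormalised using the stored
#' `norm_state`, then the windows are reassembled by overlap-discard — each
#' window contributes only its trusted centre (the `margin` samples at each
#' edge are dropped), except that the first and last windows also
#' contribute their leading/trailing edges. Where windows overlap beyond
#' the margins (tail anchoring), the later window owns the samples. With an
#' identity transform the round trip reproduces the source exactly.
#'
#' @param set the `segment_set` describing the source layout (offsets and
#'   normalisation state).
#' @param transformed_segments list of numeric windows congruent with
#'   `set$segments` (same count and width); defaults to `set$segments`.
#' @param denorm `"affine"` restores `x*sd + mean` (right for a channel
#'   that was itself Z-scored, e.g. the maternal reconstruction);
#'   `"scale"` restores `x*sd` only (right for a zero-baseline component
#'   predicted in the mixture's normalised units, e.g. the fetal
#'   reconstruction); `"none"` stitches the raw windows.
#' @return numeric vector of `set$source_length` samples.
#' @export
stitch_segments <- function(set, transformed_segments = NULL,
                            denorm = c("affine", "scale", "none")) {
  stopifnot(inherits(set, "segment_set"))
  denorm <- match.arg(denorm)
  segs <- if (is.null(transformed_segments)) set$segments else transformed_segments
  if (length(segs) != length(set$offsets))
    stop("segment count mismatch: got ", length(segs), ", expected ",
         length(set$offsets))
  if (any(vapply(segs, length, integer(1)) != set$width))
    stop("all transformed segments must have width ", set$width)
  if (denorm != "none") {
    if (is.null(set$norm_state))
      stop("segment set has no norm_state; run zscore_segments() first ",
           "or use denorm = 'none'")
    segs <- lapply(seq_along(segs), function(i) {
      s <- segs[[i]] * set$norm_state[i, "sd"]
      if (denorm == "affine") s <- s + set$norm_state[i, "mean"]
      s
    })
  }
  n <- set$source_length
  out <- numeric(n)
  nseg <- length(segs)
  for (i in seq_len(nseg)) {
    o <- set$offsets[i]
    a <- if (i == 1L) o else o + set$margin
    b <- if (i == nseg) n else min(n, set$offsets[i + 1L] + set$margin - 1L)
    if (b < a) next
    out[a:b] <- segs[[i]][(a - o + 1L):(b - o + 1L)]
  }
  out
}

#' Full conditioning chain for one record
#'
#' Band-pass (3-100 Hz), resample to 250 Hz, then window and Z-score the
#' abdominal channel. Truth channels are filtered and resampled alongside
#' and windowed at the same offsets (normalised with the *mixture's*
#' statistics so predictions denormalise consistently).
#'
#' @param rec an [ecg_record()].
#' @param channel role of the channel to window (default
#'   `"abdominal_mixture"`).
#' @return list with `record` (the filtered, resampled record), `input`
#'   (the Z-scored `segment_set` of the mixture), and, when truth channels
#'   exist, `target_fetal` / `target_maternal` (lists of windows in the
#'   mixture's normalised units).
#' @export
preprocess_record <- function(rec, channel = "abdominal_mixture") {
  rec <- bandpass_record(rec)
  rec <- resample_record(rec, 250)
  x <- record_channel(rec, channel)
  set <- zscore_segments(segment_signal(x, fs = rec$fs))
  out <- list(record = rec, input = set)
  ft <- record_channel(rec, "fetal_truth", required = FALSE)
  mt <- record_channel(rec, "maternal_truth", required = FALSE)
  win <- function(ch, affine) lapply(seq_along(set$offsets), function(i) {
    o <- set$offsets[i]
    s <- ch[o:(o + set$width - 1L)]
    mu <- if (affine) set$norm_state[i, "mean"] else 0
    (s - mu) / set$norm_state[i, "sd"]
  })
  if (!is.null(ft)) out$target_fetal <- win(ft, affine = FALSE)
  if (!is.null(mt)) out$target_maternal <- win(mt, affine = TRUE)
  out
}
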
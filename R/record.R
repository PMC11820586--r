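#' ECG record container
#'
#' An `ecg_record` holds a multichannel sampled signal together with its
#' sampling rate, a role label per channel, and R-peak annotations for the
#' fetal and maternal components. It is the single currency passed between
#' the generator, the preprocessing chain, the network and the evaluators.
#'
#' Channel roles are free repetitions of:
#' `"abdominal_mixture"`, `"fetal_truth"`, `"maternal_truth"`,
#' `"fetal_scalp_reference"`, `"fecg_pred"`, `"mecg_pred"`.
#'
#' Sample indices (R-peak annotations) are 1-based, matching R's indexing;
#' time windows elsewhere in the package are half-open `[start, end)` in
#' seconds.
#'
#' @param signals numeric matrix, samples in rows, one column per channel
#'   (a plain vector is taken as one channel). Amplitudes in millivolts or
#'   normalised units.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param channel_roles character vector of channel labels, recycled from
#'   `"abdominal_mixture"` if missing.
#' @param rpeaks_fetal,rpeaks_maternal integer sample indices (1-based,
#'   strictly increasing, within the record) of annotated R peaks.
#' @param meta free-form named list of provenance (scenario, noise level,
#'   seed, injected noise vector, ...).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signals, fs, channel_roles = NULL,
                       rpeaks_fetal = integer(), rpeaks_maternal = integer(),
                       meta = list()) {
  if (is.vector(signals)) signals <- matrix(as.numeric(signals), ncol = 1L)
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (is.null(channel_roles)) channel_roles <- rep("abdominal_mixture", ncol(signals))
  rec <- structure(list(
    signals = signals,
    fs = as.numeric(fs),
    channel_roles = as.character(channel_roles),
    rpeaks_fetal = as.integer(rpeaks_fetal),
    rpeaks_maternal = as.integer(rpeaks_maternal),
    meta = meta
  ), class = "ecg_record")
  validate_record(rec)
  rec
}

#' Validate an ECG record
#'
#' Checks the structural invariants: one shared length and sampling rate for
#' all channels, positive `fs`, role labels matching the channel count, and
#' strictly increasing in-range R-peak annotations.
#'
#' @param rec an [ecg_record()].
#' @return `rec`, invisibly; errors describe the first violated invariant.
#' @export
validate_record <- function(rec) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!is.matrix(rec$signals) || !is.numeric(rec$signals))
    stop("signals must be a numeric matrix")
  if (length(rec$fs) != 1L || !is.finite(rec$fs) || rec$fs <= 0)
    stop("fs must be a single positive number")
  if (length(rec$channel_roles) != ncol(rec$signals))
    stop("channel_roles length must equal the number of channels")
  n <- nrow(rec$signals)
  for (nm in c("rpeaks_fetal", "rpeaks_maternal")) {
    pk <- rec[[nm]]
    if (length(pk)) {
      if (any(diff(pk) <= 0)) stop(nm, " must be strictly increasing")
      if (pk[1] < 1L || pk[length(pk)] > n) stop(nm, " out of range [1, ", n, "]")
    }
  }
  invisible(rec)
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples x %d channel(s) @ %g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$fs, nrow(x$signals) / x$fs))
  cat("  roles:", paste(x$channel_roles, collapse = ", "), "\n")
  cat(sprintf("  R peaks: fetal %d, maternal %d\n",
              length(x$rpeaks_fetal), length(x$rpeaks_maternal)))
  if (length(x$meta)) {
    keep <- vapply(x$meta, function(v) is.atomic(v) && length(v) == 1L, logical(1))
    if (any(keep))
      cat("  meta:", paste(names(x$meta)[keep], unlist(x$meta[keep]),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples in a record
#' @param rec an [ecg_record()].
#' @return integer sample count.
#' @export
record_length <- function(rec) nrow(rec$signals)

#' Record duration in seconds
#' @param rec an [ecg_record()].
#' @return duration in seconds.
#' @export
record_duration <- function(rec) nrow(rec$signals) / rec$fs

#' Extract one channel by role
#'
#' @param rec an [ecg_record()].
#' @param role a channel role label; the first matching channel is returned.
#' @param required error (TRUE) or return NULL (FALSE) when absent.
#' @return numeric vector of samples, or NULL.
#' @export
record_channel <- function(rec, role, required = TRUE) {
  i <- match(role, rec$channel_roles)
  if (is.na(i)) {
    if (required) stop("record has no channel with role '", role, "'")
    return(NULL)
  }
  rec$signals[, i]
}

#' Slice a record in time
#'
#' Returns the sub-record covering the half-open window `[start_s, end_s)`
#' seconds. Annotations falling inside the window are kept and re-based to
#' the slice origin. Slicing composes: slicing `[a,b)` then `[c,d)` equals
#' slicing `[a+c, a+d)` of the original.
#'
#' @param rec an [ecg_record()].
#' @param start_s,end_s window bounds in seconds, `0 <= start_s < end_s <=`
#'   record duration.
#' @return an [ecg_record()] with the windowed samples and re-based peaks.
#' @export
slice_record <- function(rec, start_s, end_s) {
  validate_record(rec)
  dur <- record_duration(rec)
  if (!is.finite(start_s) || !is.finite(end_s) || start_s < 0 ||
      start_s >= end_s || end_s > dur + 1e-9)
    stop("require 0 <= start_s < end_s <= duration (", round(dur, 3), " s)")
  i0 <- floor(start_s * rec$fs) + 1L          # first sample in window
  i1 <- ceiling(end_s * rec$fs)               # last sample (end exclusive in time)
  i1 <- min(i1, nrow(rec$signals))
  rebase <- function(pk) {
    pk <- pk[pk >= i0 & pk <= i1]
    as.integer(pk - i0 + 1L)
  }
  out <- rec
  out$signals <- rec$signals[i0:i1, , drop = FALSE]
  out$rpeaks_fetal <- rebase(rec$rpeaks_fetal)
  out$rpeaks_maternal <- rebase(rec$rpeaks_maternal)
  if (!is.null(out$meta$noise) && length(out$meta$noise) >= i1)
    out$meta$noise <- out$meta$noise[i0:i1]
  validate_record(out)
  out
}
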
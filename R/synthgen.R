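#' Beat morphology for the Gaussian PQRST waveform model
#'
#' Each heartbeat is modelled as the sum of five Gaussian waves (P, Q, R, S,
#' T), positioned and scaled relative to the RR interval. This time-domain
#' sum-of-Gaussians model carries the full P/QRS/T morphology while staying
#' small enough to synthesise long records quickly.
#'
#' @param wave_centers five signed phase offsets from the R peak, as
#'   fractions of the RR interval, ordered P < Q < R < S < T.
#' @param wave_amplitudes five signed amplitudes in mV; the R amplitude must
#'   have the largest magnitude.
#' @param wave_widths five Gaussian standard deviations as fractions of the
#'   RR interval, all positive.
#' @return a `beat_morphology` object (named list of the three vectors).
#' @export
beat_morphology <- function(wave_centers = c(P = -0.22, Q = -0.035, R = 0,
                                             S = 0.035, T = 0.30),
                            wave_amplitudes = c(P = 0.12, Q = -0.12, R = 1.0,
                                                S = -0.25, T = 0.35),
                            wave_widths = c(P = 0.035, Q = 0.010, R = 0.013,
                                            S = 0.011, T = 0.06)) {
  stopifnot(length(wave_centers) == 5, length(wave_amplitudes) == 5,
            length(wave_widths) == 5)
  if (any(wave_widths <= 0)) stop("wave_widths must be positive")
  if (any(diff(wave_centers) <= 0))
    stop("wave_centers must be ordered P < Q < R < S < T")
  if (which.max(abs(wave_amplitudes)) != 3L)
    stop("the R wave must have the largest amplitude magnitude")
  structure(list(wave_centers = wave_centers,
                 wave_amplitudes = wave_amplitudes,
                 wave_widths = wave_widths),
            class = "beat_morphology")
}

#' Default maternal beat morphology
#' @param amplitude_mv R-peak amplitude in mV.
#' @return a [beat_morphology()].
#' @export
maternal_morphology <- function(amplitude_mv = 1.0) {
  m <- beat_morphology()
  m$wave_amplitudes <- m$wave_amplitudes * amplitude_mv
  m
}

#' Default fetal beat morphology
#'
#' The fetal QRS complex is narrower than the maternal one (roughly half the
#' width in absolute time once the shorter fetal RR interval is accounted
#' for), with proportionally smaller P and T waves.
#'
#' @param amplitude_mv R-peak amplitude in mV (before mixture rescaling).
#' @return a [beat_morphology()].
#' @export
fetal_morphology <- function(amplitude_mv = 1.0) {
  beat_morphology(
    wave_centers = c(P = -0.20, Q = -0.030, R = 0, S = 0.030, T = 0.28),
    wave_amplitudes = amplitude_mv *
      c(P = 0.08, Q = -0.10, R = 1.0, S = -0.22, T = 0.25),
    wave_widths = c(P = 0.030, Q = 0.008, R = 0.010, S = 0.009, T = 0.05))
}

#' Scenario specification for the synthetic abdominal-ECG generator
#'
#' Describes one simulated recording condition in the event taxonomy used
#' throughout the package:
#' \describe{
#'   \item{baseline}{plain abdominal mixture, no events (and by default no
#'     additive noise);}
#'   \item{C0}{baseline mixture, additive noise only;}
#'   \item{C1}{fetal movement — band-limited random amplitude modulation of
#'     the fetal component;}
#'   \item{C2}{heart-rate acceleration/deceleration — a ramp applied to the
#'     fetal (or maternal) RR sequence;}
#'   \item{C3}{uterine contraction — a slow high-amplitude EMG-like burst
#'     added to the noise;}
#'   \item{C4}{ectopic beats from fetus and mother — inserted beats with
#'     inverted polarity and widened QRS;}
#'   \item{C5-stub}{twin pregnancy stub — a second fetal component at a
#'     distinct rate.}
#' }
#' Additive noise is calibrated against the fetal component: the requested
#' `noise_snr_db` equals `10*log10(P_fetal / P_noise)`. The five standard
#' study levels are 0, 3, 6, 9 and 12 dB.
#'
#' @param scenario one of `"baseline"`, `"C0"`..`"C4"`, `"C5-stub"`.
#' @param noise_snr_db fetal-referenced noise SNR in dB — one of
#'   0, 3, 6, 9, 12 — or `NA`/`"none"` for a noise-free mixture.
#' @param maternal_hr_bpm,fetal_hr_bpm heart rates in beats/min
#'   (physiological ranges 50–140 and 100–240).
#' @param fm_amplitude_ratio fetal-to-maternal R-amplitude ratio in (0, 1).
#' @param hr_modulation optional list `list(target = "fetal"|"maternal",
#'   hr_to = <bpm>)` describing a linear heart-rate ramp (C2).
#' @param ectopic_rate ectopic beats per minute (C4).
#' @param rr_jitter_pct beat-to-beat RR jitter, percent of the mean RR.
#' @param duration_s record duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed; all randomness of one record flows through it.
#' @return a `scenario_spec` object.
#' @export
scenario_spec <- function(scenario = "C0",
                          noise_snr_db = if (identical(scenario, "baseline"))
                            NA else 6,
                          maternal_hr_bpm = 80, fetal_hr_bpm = 140,
                          fm_amplitude_ratio = 0.25, hr_modulation = NULL,
                          ectopic_rate = 4, rr_jitter_pct = 3,
                          duration_s = 300, fs = 250, seed = 1L) {
  scen <- match.arg(scenario, c("baseline", "C0", "C1", "C2", "C3", "C4",
                                "C5-stub"))
  if (identical(noise_snr_db, "none")) noise_snr_db <- NA_real_
  noise_snr_db <- as.numeric(noise_snr_db)
  if (!is.na(noise_snr_db) && !noise_snr_db %in% c(0, 3, 6, 9, 12))
    stop("noise_snr_db must be one of 0, 3, 6, 9, 12 dB (or NA for none)")
  if (maternal_hr_bpm < 50 || maternal_hr_bpm > 140)
    stop("maternal_hr_bpm outside the physiological range 50-140")
  if (fetal_hr_bpm < 100 || fetal_hr_bpm > 240)
    stop("fetal_hr_bpm outside the physiological range 100-240")
  if (fm_amplitude_ratio <= 0 || fm_amplitude_ratio >= 1)
    stop("fm_amplitude_ratio must lie in (0, 1)")
  if (scen == "C2" && is.null(hr_modulation))
    hr_modulation <- list(target = "fetal", hr_to = fetal_hr_bpm + 40)
  structure(list(scenario = scen, noise_snr_db = noise_snr_db,
                 maternal_hr_bpm = maternal_hr_bpm,
                 fetal_hr_bpm = fetal_hr_bpm,
                 fm_amplitude_ratio = fm_amplitude_ratio,
                 hr_modulation = hr_modulation, ectopic_rate = ectopic_rate,
                 rr_jitter_pct = rr_jitter_pct, duration_s = duration_s,
                 fs = fs, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Enumerate a scenario-by-noise grid
#'
#' @param scenarios scenario tokens; the default covers the baseline
#'   (noise-free) condition plus the six event scenarios.
#' @param noise_levels noise SNR levels in dB.
#' @param ... further arguments passed to every [scenario_spec()].
#' @return list of `scenario_spec` objects, one per combination.
#' @export
scenario_grid <- function(scenarios = c("baseline", "C0", "C1", "C2", "C3",
                                        "C4", "C5-stub"),
                          noise_levels = c(0, 3, 6, 9, 12), ...) {
  out <- list()
  for (sc in scenarios) for (nl in noise_levels)
    out[[length(out) + 1L]] <- scenario_spec(scenario = sc,
                                             noise_snr_db = nl, ...)
  out
}

# RR sequence (seconds) covering duration_s at hr_bpm with multiplicative
# Gaussian jitter; consumes the current RNG stream.
rr_sequence <- function(hr_bpm, duration_s, jitter_pct) {
  rr0 <- 60 / hr_bpm
  n <- ceiling(duration_s / rr0) + 5L
  rr <- rr0 * (1 + (jitter_pct / 100) * rnorm(n))
  pmax(rr, 0.25 * rr0)
}

# Render a sum-of-Gaussians beat train. beat_times in seconds; per-beat RR
# (seconds) scales the wave offsets and widths.
render_beats <- function(beat_times, rr_of_beat, n, fs, morphology) {
  x <- numeric(n)
  t <- (seq_len(n) - 1) / fs
  for (b in seq_along(beat_times)) {
    tr <- beat_times[b]; rr <- rr_of_beat[b]
    for (w in 1:5) {
      c_w <- tr + morphology$wave_centers[w] * rr
      s_w <- morphology$wave_widths[w] * rr
      a_w <- morphology$wave_amplitudes[w]
      if (a_w == 0) next
      i0 <- max(1L, floor((c_w - 5 * s_w) * fs) + 1L)
      i1 <- min(n, ceiling((c_w + 5 * s_w) * fs) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      x[idx] <- x[idx] + a_w * exp(-((t[idx] - c_w)^2) / (2 * s_w^2))
    }
  }
  x
}

#' Synthesise a single clean ECG channel
#'
#' Generates one ECG channel as a train of five-Gaussian beats. RR intervals
#' are drawn around `60/hr_bpm` with the requested jitter; the returned
#' record's R-peak annotation holds the exact sample of each R-wave centre.
#' Fully reproducible given `seed`.
#'
#' @param hr_bpm heart rate in beats/min (30–250 accepted for a single
#'   channel; mixture-level physiological checks live in [scenario_spec()]).
#' @param duration_s duration in seconds (> 0).
#' @param fs sampling rate in Hz (>= 250).
#' @param morphology a [beat_morphology()].
#' @param rr_jitter_pct beat-to-beat RR jitter, percent.
#' @param seed integer seed.
#' @param role channel role label for the result.
#' @return a one-channel [ecg_record()] with `rpeaks_fetal` or
#'   `rpeaks_maternal` populated according to `role`.
#' @export
synth_single_ecg <- function(hr_bpm, duration_s, fs = 250,
                             morphology = maternal_morphology(),
                             rr_jitter_pct = 3, seed = 1L,
                             role = "maternal_truth") {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs < 250) stop("fs must be at least 250 Hz")
  if (hr_bpm < 30 || hr_bpm > 250) stop("non-physiological heart rate")
  set.seed(as.integer(seed))
  rr <- rr_sequence(hr_bpm, duration_s, rr_jitter_pct)
  first <- 0.5 * rr[1]
  beat_times <- first + c(0, cumsum(rr[-length(rr)]))
  keep <- beat_times < duration_s - 1e-9
  beat_times <- beat_times[keep]
  rr_of_beat <- rr[seq_along(beat_times)]
  n <- round(duration_s * fs)
  x <- render_beats(beat_times, rr_of_beat, n, fs, morphology)
  peaks <- round(beat_times * fs) + 1L
  peaks <- peaks[peaks >= 1L & peaks <= n]
  args <- list(signals = x, fs = fs, channel_roles = role,
               meta = list(hr_bpm = hr_bpm, seed = as.integer(seed),
                           rr_jitter_pct = rr_jitter_pct))
  if (role == "fetal_truth") args$rpeaks_fetal <- peaks
  else args$rpeaks_maternal <- peaks
  do.call(ecg_record, args)
}

# Composite noise: white + 0.3 Hz baseline-wander drift + 50 Hz powerline,
# scaled to total power `p_target`. Power shares 0.6/0.25/0.15.
make_noise <- function(n, fs, p_target) {
  t <- (seq_len(n) - 1) / fs
  w <- rnorm(n)
  bw <- sin(2 * pi * 0.3 * t + runif(1, 0, 2 * pi))
  pl <- sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
  scale_to <- function(x, p) x * sqrt(p / max(mean(x^2), 1e-300))
  nz <- scale_to(w, 0.60 * p_target) + scale_to(bw, 0.25 * p_target) +
    scale_to(pl, 0.15 * p_target)
  nz * sqrt(p_target / mean(nz^2))
}

#' Mix maternal and fetal ECGs into an abdominal recording
#'
#' Builds the three-channel record `[abdominal_mixture, maternal_truth,
#' fetal_truth]`. The fetal component is rescaled so that its median R-peak
#' amplitude is `fm_amplitude_ratio` times the maternal one; additive noise
#' (white + 0.3 Hz baseline wander + 50 Hz powerline) is scaled so that
#' `10*log10(P_fetal/P_noise)` equals `noise_snr_db` exactly. The injected
#' noise vector is kept in `meta$noise`, so
#' `mixture - maternal_truth - fetal_truth == noise` holds to machine
#' precision.
#'
#' @param mecg one-channel maternal [ecg_record()] with maternal R peaks.
#' @param fecg one-channel fetal [ecg_record()] with fetal R peaks.
#' @param spec a [scenario_spec()]; only the amplitude-ratio and noise
#'   fields are used here (events are applied by
#'   [apply_scenario_events()]).
#' @return a three-channel [ecg_record()] carrying both annotation sets.
#' @export
mix_abdominal <- function(mecg, fecg, spec) {
  validate_record(mecg); validate_record(fecg)
  if (mecg$fs != fecg$fs) stop("maternal and fetal records must share fs")
  if (nrow(mecg$signals) != nrow(fecg$signals))
    stop("maternal and fetal records must share length")
  m <- mecg$signals[, 1]; f <- fecg$signals[, 1]
  rp_m <- mecg$rpeaks_maternal; rp_f <- fecg$rpeaks_fetal
  if (!length(rp_m) || !length(rp_f))
    stop("both inputs must carry R-peak annotations")
  amp_m <- stats::median(abs(m[rp_m])); amp_f <- stats::median(abs(f[rp_f]))
  f <- f * (spec$fm_amplitude_ratio * amp_m / max(amp_f, 1e-12))
  n <- length(m)
  set.seed(spec$seed + 104729L)  # noise stream distinct from beat stream
  if (!is.na(spec$noise_snr_db)) {
    p_f <- mean(f^2)
    nz <- make_noise(n, mecg$fs, p_f / 10^(spec$noise_snr_db / 10))
  } else nz <- numeric(n)
  mix <- m + f + nz
  ecg_record(cbind(mix, m, f), fs = mecg$fs,
             channel_roles = c("abdominal_mixture", "maternal_truth",
                               "fetal_truth"),
             rpeaks_fetal = rp_f, rpeaks_maternal = rp_m,
             meta = list(noise = nz, scenario = spec$scenario,
                         noise_snr_db = spec$noise_snr_db,
                         fm_amplitude_ratio = spec$fm_amplitude_ratio,
                         seed = spec$seed))
}

# Time-warp one component channel so its instantaneous rate ramps linearly
# from 1 to `factor` times the original over the record; annotations are
# mapped through the inverse warp.
warp_channel <- function(x, peaks, fs, factor) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  dur <- (n - 1) / fs
  # phase(t) = integral of rate ratio r(s) = 1 + (factor-1) * s/dur
  phase <- t * (1 + (factor - 1) * t / (2 * dur))
  y <- stats::approx(t, x, xout = pmin(phase, dur), rule = 2)$y
  # new peak time t' solves phase(t') = old peak time
  tp <- (peaks - 1) / fs
  a <- (factor - 1) / (2 * dur)
  tnew <- if (abs(a) < 1e-12) tp else (-1 + sqrt(1 + 4 * a * tp)) / (2 * a)
  pk <- round(tnew * fs) + 1L
  list(x = y, peaks = as.integer(sort(unique(pk[pk >= 1L & pk <= n]))))
}

# Insert ectopic beats (inverted polarity, doubled QRS width) into a
# component channel at Poisson times, avoiding existing beats.
insert_ectopics <- function(x, peaks, fs, rate_per_min, morphology, rr_s) {
  n <- length(x); dur <- n / fs
  k <- rpois(1, rate_per_min * dur / 60)
  if (k == 0) return(list(x = x, peaks = peaks, ectopic = integer()))
  ect <- morphology
  ect$wave_amplitudes <- -morphology$wave_amplitudes
  ect$wave_widths <- morphology$wave_widths * c(1, 2, 2, 2, 1)
  # draw each ectopic time mid-diastole: away from existing R waves by at
  # least a quarter RR (retry a bounded number of times)
  pk_t <- (peaks - 1) / fs
  times <- numeric(0)
  for (i in seq_len(k)) {
    for (try in 1:50) {
      tt <- runif(1, 0.05 * dur, 0.95 * dur)
      if (all(abs(tt - pk_t) > 0.25 * rr_s) &&
          (!length(times) || all(abs(tt - times) > 0.5 * rr_s))) {
        times <- c(times, tt)
        break
      }
    }
  }
  times <- sort(times)
  if (!length(times)) return(list(x = x, peaks = peaks, ectopic = integer()))
  x <- x + render_beats(times, rep(rr_s, length(times)), n, fs, ect)
  epk <- round(times * fs) + 1L
  all_pk <- sort(unique(c(peaks, epk)))
  list(x = x, peaks = as.integer(all_pk), ectopic = as.integer(epk))
}

#' Apply a scenario's physiological events to a mixed record
#'
#' Modifies the ground-truth component channels of a mixture produced by
#' [mix_abdominal()] according to the event taxonomy (see
#' [scenario_spec()]), updates the annotations to match the modified beat
#' times, rebuilds the mixture channel as `maternal + fetal + noise`, and
#' rescales the stored noise so the requested fetal-referenced SNR still
#' holds after the event changed the fetal power. `C0` leaves the record
#' unchanged (its only deviation from the noise-free baseline is the
#' additive noise already injected at mixing time).
#'
#' @param record a mixed [ecg_record()] with truth channels and
#'   `meta$noise`.
#' @param spec a [scenario_spec()].
#' @return the modified [ecg_record()]; event bookkeeping (ectopic beat
#'   indices, second-twin R peaks) is recorded in `meta`.
#' @export
apply_scenario_events <- function(record, spec) {
  validate_record(record)
  if (!all(c("maternal_truth", "fetal_truth") %in% record$channel_roles))
    stop("record must carry maternal_truth and fetal_truth channels")
  scen <- spec$scenario
  if (!scen %in% c("baseline", "C0", "C1", "C2", "C3", "C4", "C5-stub"))
    stop("unknown scenario token '", scen, "'")
  fs <- record$fs
  m <- record_channel(record, "maternal_truth")
  f <- record_channel(record, "fetal_truth")
  nz <- record$meta$noise
  if (is.null(nz)) nz <- numeric(length(f))
  set.seed(spec$seed + 224737L)  # event stream
  meta <- record$meta
  rp_f <- record$rpeaks_fetal; rp_m <- record$rpeaks_maternal

  if (scen == "C1") {
    mod <- rnorm(length(f))
    bf <- signal::butter(2, 0.5 / (fs / 2), "low")
    mod <- as.numeric(signal::filtfilt(bf, mod))
    mod <- 0.25 * mod / max(stats::sd(mod), 1e-12)
    f <- f * pmax(1 + mod, 0.2)
  } else if (scen == "C2") {
    hm <- spec$hr_modulation
    if (is.null(hm)) hm <- list(target = "fetal", hr_to = spec$fetal_hr_bpm + 40)
    if (identical(hm$target, "maternal")) {
      wz <- warp_channel(m, rp_m, fs, hm$hr_to / spec$maternal_hr_bpm)
      m <- wz$x; rp_m <- wz$peaks
    } else {
      wz <- warp_channel(f, rp_f, fs, hm$hr_to / spec$fetal_hr_bpm)
      f <- wz$x; rp_f <- wz$peaks
    }
    meta$hr_modulation_to <- hm$hr_to
  } else if (scen == "C3") {
    n <- length(m); dur <- n / fs
    centre <- runif(1, 0.3, 0.7) * dur
    width <- min(10, 0.3 * dur)
    t <- (seq_len(n) - 1) / fs
    env <- exp(-((t - centre)^2) / (2 * (width / 2.355)^2))  # FWHM = width
    bf <- signal::butter(2, c(20, 80) / (fs / 2), "pass")
    emg <- as.numeric(signal::filtfilt(bf, rnorm(n)))
    emg <- emg / max(stats::sd(emg), 1e-12)
    burst <- 2 * sqrt(mean(m^2)) * env * emg
    nz <- nz + burst
    meta$contraction_centre_s <- centre
  } else if (scen == "C4") {
    rr_f <- 60 / spec$fetal_hr_bpm; rr_m <- 60 / spec$maternal_hr_bpm
    ef <- insert_ectopics(f, rp_f, fs, spec$ectopic_rate,
                          fetal_morphology(max(abs(f[rp_f]))), rr_f)
    f <- ef$x; rp_f <- ef$peaks; meta$ectopic_fetal <- ef$ectopic
    em <- insert_ectopics(m, rp_m, fs, spec$ectopic_rate,
                          maternal_morphology(max(abs(m[rp_m]))), rr_m)
    m <- em$x; rp_m <- em$peaks; meta$ectopic_maternal <- em$ectopic
  } else if (scen == "C5-stub") {
    hr2 <- min(240, spec$fetal_hr_bpm + 25)
    twin <- synth_single_ecg(hr2, length(f) / fs, fs,
                             morphology = fetal_morphology(),
                             rr_jitter_pct = spec$rr_jitter_pct,
                             seed = spec$seed + 393241L, role = "fetal_truth")
    x2 <- twin$signals[, 1]
    x2 <- x2 * (0.8 * max(abs(f[rp_f])) / max(max(abs(x2)), 1e-12))
    f <- f + x2
    meta$rpeaks_fetal_twin <- twin$rpeaks_fetal
  }

  # keep the fetal-referenced noise SNR at its requested value
  if (!is.na(spec$noise_snr_db) && mean(nz^2) > 0) {
    p_target <- mean(f^2) / 10^(spec$noise_snr_db / 10)
    nz <- nz * sqrt(p_target / mean(nz^2))
  }
  meta$noise <- nz
  sig <- record$signals
  sig[, match("maternal_truth", record$channel_roles)] <- m
  sig[, match("fetal_truth", record$channel_roles)] <- f
  sig[, match("abdominal_mixture", record$channel_roles)] <- m + f + nz
  out <- record
  out$signals <- sig
  out$rpeaks_fetal <- rp_f
  out$rpeaks_maternal <- rp_m
  out$meta <- meta
  validate_record(out)
  out
}

#' Simulate one complete abdominal recording
#'
#' Convenience wrapper running the whole generator for one
#' [scenario_spec()]: synthesise the maternal and fetal components, mix
#' them with calibrated noise, then apply the scenario's events.
#'
#' @param spec a [scenario_spec()].
#' @return a three-channel [ecg_record()] with ground truth and
#'   annotations.
#' @export
simulate_record <- function(spec) {
  mecg <- synth_single_ecg(spec$maternal_hr_bpm, spec$duration_s, spec$fs,
                           morphology = maternal_morphology(),
                           rr_jitter_pct = spec$rr_jitter_pct,
                           seed = spec$seed, role = "maternal_truth")
  fecg <- synth_single_ecg(spec$fetal_hr_bpm, spec$duration_s, spec$fs,
                           morphology = fetal_morphology(),
                           rr_jitter_pct = spec$rr_jitter_pct,
                           seed = spec$seed + 15485863L, role = "fetal_truth")
  rec <- mix_abdominal(mecg, fecg, spec)
  apply_scenario_events(rec, spec)
}

#' Generate a dataset of synthetic records on disk
#'
#' Writes `n_records` records per scenario specification plus a manifest
#' table (`manifest.tsv`: path, scenario, noise level, seed, duration, fs,
#' heart rates). Every record gets a distinct seed derived from its spec's
#' seed and replicate index, so the dataset is fully reproducible from the
#' manifest alone.
#'
#' @param n_records replicates per spec (>= 1).
#' @param spec_grid a list of [scenario_spec()] objects (see
#'   [scenario_grid()]); a single spec is accepted.
#' @param out_dir output directory (created if needed).
#' @param format on-disk record layout, `"csv"` or `"wfdb"`.
#' @return the manifest as a data.frame, invisibly; also written to
#'   `<out_dir>/manifest.tsv`.
#' @export
make_dataset <- function(n_records, spec_grid, out_dir, format = "csv") {
  if (n_records < 1) stop("n_records must be >= 1")
  if (inherits(spec_grid, "scenario_spec")) spec_grid <- list(spec_grid)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  rows <- list()
  for (j in seq_along(spec_grid)) {
    for (i in seq_len(n_records)) {
      sp <- spec_grid[[j]]
      sp$seed <- as.integer((sp$seed + 7919L * (j - 1L) + i - 1L) %% 2147483647L)
      rec <- simulate_record(sp)
      name <- sprintf("rec_%s_n%s_%03d",
                      gsub("[^A-Za-z0-9]", "", sp$scenario),
                      ifelse(is.na(sp$noise_snr_db), "none",
                             sp$noise_snr_db), length(rows) + 1L)
      write_record(rec, file.path(out_dir, name), format = format)
      rows[[length(rows) + 1L]] <- data.frame(
        path = name, format = format, scenario = sp$scenario,
        noise_snr_db = sp$noise_snr_db, seed = sp$seed,
        duration_s = sp$duration_s, fs = sp$fs,
        maternal_hr_bpm = sp$maternal_hr_bpm,
        fetal_hr_bpm = sp$fetal_hr_bpm,
        fm_amplitude_ratio = sp$fm_amplitude_ratio,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Load the records listed in a dataset manifest
#'
#' @param manifest path to a `manifest.tsv` written by [make_dataset()], or
#'   the directory containing it.
#' @return list of [ecg_record()] objects.
#' @export
load_dataset <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.tsv")
  if (!file.exists(manifest)) stop("missing manifest: ", manifest)
  tab <- utils::read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  lapply(seq_len(nrow(tab)), function(i) {
    base <- file.path(dir, tab$path[i])
    if (identical(tab$format[i], "wfdb")) read_wfdb_record(base)
    else read_record_csv(base)
  })
}
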
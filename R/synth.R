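# Class-conditioned synthetic physiology.
#
# The generator encodes the class structure the downstream features are
# meant to detect: arousal drives heart rate, heart-rate variability and
# skin-conductance-response rate; valence (the weaker axis, as in the
# empirical literature) drives SCR amplitude scale and the sign of the slow
# skin-temperature drift. Per-subject offsets and an affine "sensor-brand"
# shift between recording environments emulate the obstacles the
# calibration model exists to remove.

#' Draw per-subject physiological offsets
#'
#' Each simulated subject carries a stable resting heart-rate offset, an
#' electrodermal gain and baseline, and a skin-temperature baseline, drawn
#' once per subject.
#'
#' @param seed integer seed; the draw is a pure function of it.
#' @return An object of class `subject_effect`: list with `hr_offset_bpm`
#'   (U(-10, 10)), `eda_gain` (U(0.7, 1.4)), `eda_baseline_us` (U(2, 8)),
#'   `st_baseline_c` (U(31, 34)) and `rng_seed`.
#' @export
gen_subject_effect <- function(seed) {
  with_seed(seed, {
    structure(list(
      hr_offset_bpm  = stats::runif(1, -10, 10),
      eda_gain       = stats::runif(1, 0.7, 1.4),
      eda_baseline_us = stats::runif(1, 2, 8),
      st_baseline_c  = stats::runif(1, 31, 34),
      rng_seed       = as.integer(seed)
    ), class = "subject_effect")
  })
}

neutral_subject_effect <- function() {
  structure(list(hr_offset_bpm = 0, eda_gain = 1, eda_baseline_us = 5,
                 st_baseline_c = 32.5, rng_seed = 0L),
            class = "subject_effect")
}

#' Generate a class-conditioned RR-interval series
#'
#' Beat-to-beat (RR) intervals in ms with arousal-dependent mean heart rate
#' (70 bpm low arousal, 85 bpm high, plus the subject's offset),
#' arousal-dependent beat-to-beat jitter (SD 40 ms low / 18 ms high) and
#' sinusoidal autonomic modulation at 0.1 Hz (LF) and 0.25 Hz (HF) whose
#' amplitude ratio is >= 2:1 for high arousal and <= 1:2 for low arousal.
#'
#' @param label an [emotion_label()].
#' @param effect a [gen_subject_effect()] result.
#' @param duration_s trial length in seconds (>= 60).
#' @param seed integer seed.
#' @return numeric vector of RR intervals (ms) whose cumulative sum covers
#'   `duration_s`.
#' @export
gen_rr_series <- function(label, effect, duration_s, seed) {
  stopifnot(inherits(label, "emotion_label"), inherits(effect, "subject_effect"))
  if (duration_s < 60)
    stop_named("short_trial", "duration_s must be >= 60 s")
  high_ar <- label$arousal_level == "high"
  hr <- (if (high_ar) 85 else 70) + effect$hr_offset_bpm
  rr_mean <- 60000 / hr
  jitter_sd <- if (high_ar) 18 else 40
  lf_amp <- if (high_ar) 24 else 12
  hf_amp <- if (high_ar) 8 else 30
  n_max <- ceiling(duration_s * 1000 / rr_mean * 1.5) + 20
  with_seed(seed, {
    eps <- stats::rnorm(n_max, 0, jitter_sd)
    rr <- numeric(n_max)
    t_ms <- 0
    n <- 0L
    for (i in seq_len(n_max)) {
      t_s <- t_ms / 1000
      val <- rr_mean +
        lf_amp * sin(2 * pi * 0.10 * t_s) +
        hf_amp * sin(2 * pi * 0.25 * t_s) +
        eps[i]
      val <- min(max(val, 300), 2000)
      n <- n + 1L
      rr[n] <- val
      t_ms <- t_ms + val
      if (t_ms >= duration_s * 1000) break
    }
    rr <- rr[seq_len(n)]
    if (n < 30L)
      stop_named("short_trial", "duration too short to hold >= 30 beats")
    rr
  })
}

#' Render an RR series as a synthetic ECG waveform
#'
#' One dominant R spike per beat: a Gaussian template of amplitude 1 mV and
#' ~20 ms width centered at each cumulative RR time, over white baseline
#' noise. Morphologically minimal by design -- the only property required of
#' it is that an R-peak detector recovers the injected beat times.
#'
#' @param rr_ms RR intervals in ms (non-empty).
#' @param fs sampling rate in Hz (>= 128).
#' @param duration_s optional output duration; defaults to the RR sum plus a
#'   quarter second.
#' @param noise_sd baseline noise SD in mV (default 0.02; 0 gives a
#'   noise-free waveform).
#' @param seed integer seed for the noise.
#' @return a `physio_signal` (sensor `"ecg"`) with attribute `peak_times_s`
#'   holding the injected R-peak times.
#' @export
gen_ecg <- function(rr_ms, fs = 256, duration_s = NULL, noise_sd = 0.02,
                    seed = 0L) {
  if (length(rr_ms) == 0L) stop_named("empty_rr", "rr_ms is empty")
  if (fs < 128) stop_named("invalid_fs", "fs must be >= 128 Hz")
  peak_t <- cumsum(rr_ms) / 1000
  if (is.null(duration_s)) duration_s <- peak_t[length(peak_t)] + 0.25
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- if (noise_sd > 0) with_seed(seed, stats::rnorm(n, 0, noise_sd)) else numeric(n)
  sd_s <- 0.008  # Gaussian sigma; full width at half maximum ~ 19 ms
  for (pt in peak_t) {
    if (pt > duration_s) break
    i0 <- max(1L, floor((pt - 4 * sd_s) * fs) + 1L)
    i1 <- min(n, ceiling((pt + 4 * sd_s) * fs) + 1L)
    idx <- i0:i1
    x[idx] <- x[idx] + exp(-0.5 * ((t[idx] - pt) / sd_s)^2)
  }
  out <- physio_signal(x, fs, "ecg")
  attr(out, "peak_times_s") <- peak_t[peak_t <= duration_s]
  out
}

# Slow (< 0.01 Hz) random drift: a Gaussian random walk on ~100 s control
# points, spline-interpolated onto the sample grid.
slow_drift <- function(duration_s, fs, step_sd) {
  m <- max(3L, ceiling(duration_s / 100) + 2L)
  ctrl_t <- seq(0, duration_s, length.out = m)
  ctrl <- cumsum(stats::rnorm(m, 0, step_sd))
  ctrl <- ctrl - ctrl[1]
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  stats::spline(ctrl_t, ctrl, xout = t)$y
}

# Canonical biexponential SCR kernel (rise tau 1 s, decay tau 4 s),
# normalized to unit peak.
scr_kernel <- function(fs, len_s = 20) {
  t <- seq(0, len_s, by = 1 / fs)
  k <- exp(-t / 4) - exp(-t / 1)
  k / max(k)
}

#' Generate a class-conditioned electrodermal activity signal
#'
#' Tonic level = subject baseline + slow drift + 1.5 uS increment under high
#' arousal; phasic skin-conductance responses are biexponential bumps (1 s
#' rise, 4 s decay) arriving as a Poisson process at 8/min (high arousal) or
#' 2/min (low arousal), amplitudes U(0.1, 1) uS scaled by the subject's EDA
#' gain, with +0.3 uS added to the amplitude scale under high valence.
#'
#' @inheritParams gen_rr_series
#' @param fs sampling rate in Hz.
#' @return a `physio_signal` (sensor `"eda"`, all samples > 0) with
#'   attribute `scr_events`: data frame of injected event times and
#'   amplitudes.
#' @export
gen_eda <- function(label, effect, duration_s, fs = 4, seed = 0L) {
  stopifnot(inherits(label, "emotion_label"), inherits(effect, "subject_effect"))
  high_ar <- label$arousal_level == "high"
  high_va <- label$valence_level == "high"
  rate_per_min <- if (high_ar) 8 else 2
  n <- round(duration_s * fs)
  with_seed(seed, {
    tonic <- effect$eda_baseline_us + slow_drift(duration_s, fs, 0.15) +
      (if (high_ar) 1.5 else 0)
    n_ev <- stats::rpois(1, rate_per_min * duration_s / 60)
    ev_t <- sort(stats::runif(n_ev, 0, max(duration_s - 5, 1)))
    amp_scale <- effect$eda_gain
    amps <- (stats::runif(n_ev, 0.1, 1.0) + (if (high_va) 0.3 else 0)) * amp_scale
    x <- tonic
    if (n_ev > 0) {
      ker <- scr_kernel(fs)
      for (j in seq_len(n_ev)) {
        i0 <- floor(ev_t[j] * fs) + 1L
        idx <- i0:min(n, i0 + length(ker) - 1L)
        x[idx] <- x[idx] + amps[j] * ker[seq_along(idx)]
      }
    }
    x <- pmax(x, 0.01)
    out <- physio_signal(x, fs, "eda")
    attr(out, "scr_events") <- data.frame(time_s = ev_t, amplitude_us = amps)
    out
  })
}

#' Generate a class-conditioned skin-temperature signal
#'
#' Subject baseline plus slow drift: a directional thermal trend
#' (0.005 degC/s, the slow peripheral warming/cooling seen over a seated
#' trial) plus a random walk of SD 0.1 degC. The mean is shifted -0.4 degC
#' under high arousal (peripheral vasoconstriction proxy) and the drift
#' trend's sign is flipped under high valence (warming for high, cooling
#' for low). Samples are clamped to the physiological range 25-40 degC.
#'
#' @inheritParams gen_eda
#' @return a `physio_signal` (sensor `"st"`).
#' @export
gen_st <- function(label, effect, duration_s, fs = 4, seed = 0L) {
  stopifnot(inherits(label, "emotion_label"), inherits(effect, "subject_effect"))
  high_ar <- label$arousal_level == "high"
  high_va <- label$valence_level == "high"
  with_seed(seed, {
    t <- (seq_len(round(duration_s * fs)) - 1) / fs
    trend <- 0.008 * t  # gradual peripheral warming from trial onset
    if (!high_va) trend <- -trend
    drift <- slow_drift(duration_s, fs, 0.1)
    x <- effect$st_baseline_c + trend + drift + (if (high_ar) -0.4 else 0)
    physio_signal(pmin(pmax(x, 25), 40), fs, "st")
  })
}

#' Describe an affine sensor-brand domain shift
#'
#' Models systematic measurement differences between recording environments
#' (different sensor brands): each channel's raw samples are transformed as
#' `gain * x + offset`, optionally with additive white measurement noise.
#'
#' @param ecg_gain,eda_gain,st_gain multiplicative gains (> 0).
#' @param ecg_offset,eda_offset,st_offset additive offsets in sensor units.
#' @param feature_noise_sd SD of additive white noise applied to each
#'   channel (in that channel's units, scaled by its gain); default 0.
#' @return an object of class `domain_shift`.
#' @export
domain_shift <- function(ecg_gain = 1, ecg_offset = 0,
                         eda_gain = 1, eda_offset = 0,
                         st_gain = 1, st_offset = 0,
                         feature_noise_sd = 0) {
  gains <- c(ecg_gain, eda_gain, st_gain)
  if (any(!is.finite(gains)) || any(gains <= 0))
    stop_named("invalid_shift", "domain-shift gains must be positive")
  if (feature_noise_sd < 0)
    stop_named("invalid_shift", "feature_noise_sd must be >= 0")
  structure(list(
    ecg = c(gain = ecg_gain, offset = ecg_offset),
    eda = c(gain = eda_gain, offset = eda_offset),
    st  = c(gain = st_gain,  offset = st_offset),
    feature_noise_sd = feature_noise_sd
  ), class = "domain_shift")
}

is_identity_shift <- function(shift) {
  is.null(shift) ||
    (all(vapply(shift[c("ecg", "eda", "st")],
                function(p) p[["gain"]] == 1 && p[["offset"]] == 0, TRUE)) &&
       shift$feature_noise_sd == 0)
}

apply_shift_signal <- function(sig, shift, seed) {
  if (is.null(shift)) return(sig)
  p <- shift[[sig$sensor]]
  x <- p[["gain"]] * sig$samples + p[["offset"]]
  if (shift$feature_noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(length(x), 0,
                                          shift$feature_noise_sd * p[["gain"]]))
  }
  out <- physio_signal(x, sig$fs, sig$sensor)
  attributes(out) <- utils::modifyList(attributes(sig), attributes(out))
  out
}

#' Generate one synthetic trial
#'
#' @param subject_id,trial_id identifiers; with `seed` they determine the
#'   trial's private RNG stream.
#' @param label an [emotion_label()].
#' @param effect the subject's [gen_subject_effect()].
#' @param duration_s trial length in seconds.
#' @param shift optional [domain_shift()] applied to every sample.
#' @param seed integer master seed.
#' @return an object of class `trial_recording`: list with `subject_id`,
#'   `trial_id`, `ecg`, `eda`, `st` and `label`.
#' @export
gen_trial <- function(subject_id, trial_id, label, effect, duration_s,
                      shift = NULL, seed = 0L) {
  rr <- gen_rr_series(label, effect, duration_s,
                      derive_seed(seed, subject_id, trial_id, "rr"))
  ecg <- gen_ecg(rr, fs = 256, duration_s = duration_s,
                 seed = derive_seed(seed, subject_id, trial_id, "ecg"))
  eda <- gen_eda(label, effect, duration_s, fs = 4,
                 seed = derive_seed(seed, subject_id, trial_id, "eda"))
  st <- gen_st(label, effect, duration_s, fs = 4,
               seed = derive_seed(seed, subject_id, trial_id, "st"))
  if (!is.null(shift) && !is_identity_shift(shift)) {
    ecg <- apply_shift_signal(ecg, shift, derive_seed(seed, subject_id, trial_id, "sh-ecg"))
    eda <- apply_shift_signal(eda, shift, derive_seed(seed, subject_id, trial_id, "sh-eda"))
    st  <- apply_shift_signal(st,  shift, derive_seed(seed, subject_id, trial_id, "sh-st"))
  }
  structure(list(subject_id = subject_id, trial_id = trial_id,
                 ecg = ecg, eda = eda, st = st, label = label),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s/%s, %.0f s, class %d (%s)\n",
              x$subject_id, x$trial_id, signal_duration(x$eda),
              x$label$class_index, class_names()[x$label$class_index + 1L]))
  invisible(x)
}

#' Generate a class-balanced multi-subject dataset
#'
#' Subjects receive independent physiological offsets; each subject's trials
#' are balanced over the four valence/arousal classes as evenly as
#' divisibility allows, with raw 1-9 ratings drawn uniformly within the
#' matching half of the scale. Deterministic given `seed`: each trial's
#' stream is derived from (seed, subject, trial), so adding subjects never
#' perturbs existing ones.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param trials_per_subject trials per subject (>= 4).
#' @param duration_s trial length in seconds.
#' @param shift optional [domain_shift()] applied to every signal.
#' @param seed integer master seed.
#' @param subject_prefix prefix for subject ids (default `"S"`); use a
#'   different prefix to draw a disjoint population (fresh subject effects)
#'   for a second recording environment.
#' @return list of `trial_recording` objects.
#' @export
gen_dataset <- function(n_subjects, trials_per_subject, duration_s = 120,
                        shift = NULL, seed = 0L, subject_prefix = "S") {
  if (n_subjects < 2) stop_named("invalid_counts", "n_subjects must be >= 2")
  if (trials_per_subject < 4)
    stop_named("invalid_counts", "trials_per_subject must be >= 4")
  trials <- vector("list", n_subjects * trials_per_subject)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("%s%02d", subject_prefix, s)
    effect <- gen_subject_effect(derive_seed(seed, sid, "effect"))
    classes <- rep(0:3, length.out = trials_per_subject)
    for (tr in seq_len(trials_per_subject)) {
      tid <- sprintf("T%02d", tr)
      cls <- classes[tr]
      raw <- with_seed(derive_seed(seed, sid, tid, "label"), {
        v <- if (cls >= 2) sample(6:9, 1) else sample(1:5, 1)
        a <- if (cls %% 2 == 1) sample(6:9, 1) else sample(1:5, 1)
        c(v, a)
      })
      k <- k + 1L
      trials[[k]] <- gen_trial(sid, tid, emotion_label(raw[1], raw[2]),
                               effect, duration_s, shift, seed)
    }
  }
  trials
}

#' Write a dataset of trials to a directory tree
#'
#' One directory per trial containing `ecg.csv`, `eda.csv`, `st.csv`
#' (columns `time_s,value`) and `meta.json`, plus a top-level
#' `manifest.csv`.
#'
#' @param trials list of `trial_recording` objects.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(trials, function(tr) {
    sub <- file.path(dir, paste(tr$subject_id, tr$trial_id, sep = "_"))
    dir.create(sub, showWarnings = FALSE)
    write_signal_csv(tr$ecg, file.path(sub, "ecg.csv"))
    write_signal_csv(tr$eda, file.path(sub, "eda.csv"))
    write_signal_csv(tr$st, file.path(sub, "st.csv"))
    jsonlite::write_json(list(subject_id = tr$subject_id, trial_id = tr$trial_id,
                              valence_raw = tr$label$valence_raw,
                              arousal_raw = tr$label$arousal_raw),
                         file.path(sub, "meta.json"), auto_unbox = TRUE)
    data.frame(subject_id = tr$subject_id, trial_id = tr$trial_id,
               dir = basename(sub), valence_raw = tr$label$valence_raw,
               arousal_raw = tr$label$arousal_raw)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir dataset directory containing `manifest.csv`.
#' @return list of `trial_recording` objects.
#' @export
read_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         colClasses = c(subject_id = "character",
                                        trial_id = "character",
                                        dir = "character"))
  lapply(seq_len(nrow(man)), function(i) {
    sub <- file.path(dir, man$dir[i])
    structure(list(
      subject_id = man$subject_id[i], trial_id = man$trial_id[i],
      ecg = read_signal_csv(file.path(sub, "ecg.csv"), "ecg"),
      eda = read_signal_csv(file.path(sub, "eda.csv"), "eda"),
      st = read_signal_csv(file.path(sub, "st.csv"), "st"),
      label = emotion_label(man$valence_raw[i], man$arousal_raw[i])
    ), class = "trial_recording")
  })
}
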
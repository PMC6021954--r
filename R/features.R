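# Feature extraction: 12 EDA features, 8 ECG (HRV) features and 3 (or 5)
# skin-temperature statistics per trial.

#' Default feature-extraction configuration
#'
#' @param scr_threshold_us minimum trough-to-peak rise (in microsiemens) for
#'   a skin-conductance response to count as significant; default 0.05.
#' @param st_extended if `TRUE` (default), skin temperature contributes
#'   five features (mean, max, SD, min, mean first difference), for the
#'   full 12 + 8 + 5 = 25-feature vector; `FALSE` keeps only the three
#'   central moments (23 features).
#' @param welch_segment_s Welch segment length in seconds for the HRV
#'   spectrum; default 64.
#' @param scr_vlf_band if `TRUE` (default) the SCR event rate is counted on
#'   the phasic signal band-limited to 0-0.1 Hz; `FALSE` counts events on
#'   the raw phasic signal.
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(scr_threshold_us = 0.05, st_extended = TRUE,
                           welch_segment_s = 64, scr_vlf_band = TRUE) {
  if (scr_threshold_us <= 0)
    stop_named("invalid_config", "scr_threshold_us must be > 0")
  if (welch_segment_s <= 0)
    stop_named("invalid_config", "welch_segment_s must be > 0")
  structure(list(scr_threshold_us = scr_threshold_us,
                 st_extended = isTRUE(st_extended),
                 welch_segment_s = welch_segment_s,
                 scr_vlf_band = isTRUE(scr_vlf_band)),
            class = "feature_config")
}

#' Names of the extracted features, in their fixed order
#' @param config a [feature_config()].
#' @return character vector of length 23 (default) or 25 (extended ST).
#' @export
feature_names <- function(config = feature_config()) {
  c("scl_mean", "scl_std", "scl_max", "scl_min", "scl_rms",
    "scl_d1_mean", "scl_d2_mean", "scl_negslope_mean",
    "scr_rate_vlf", "scr_first_latency", "scr_amp_sum", "scr_area_sum",
    "nn_mean", "sdnn", "rmssd", "nn50", "pnn50",
    "lf_power", "hf_power", "lf_hf_ratio",
    "st_mean", "st_max", "st_std",
    if (config$st_extended) c("st_min", "st_d1_mean"))
}

# Zero-phase Butterworth low-pass with reflection padding, so very low
# cut-offs do not leak start-up transients into the signal ends.
zerophase_lowpass <- function(x, fs, cutoff_hz, order = 2) {
  w <- cutoff_hz / (fs / 2)
  bf <- signal::butter(order, w, type = "low")
  n <- length(x)
  mu <- mean(x)
  x <- x - mu  # filter the fluctuation only; exact DC reconstruction
  pad <- min(n - 1L, ceiling(3 * fs / cutoff_hz))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1):(pad + n)] + mu
}

## ---- ECG ----------------------------------------------------------------

#' Detect R peaks in an ECG signal
#'
#' Pan-Tompkins-style detector: band-pass 5-30 Hz (zero-phase Butterworth),
#' squaring, 150 ms moving-window integration, adaptive threshold, then
#' peak refinement on the band-passed signal. A 200 ms refractory gap is
#' enforced.
#'
#' @param ecg a `physio_signal` with `fs >= 128` and duration >= 10 s.
#' @return integer vector of strictly increasing peak sample indices
#'   (1-based).
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "physio_signal"))
  fs <- ecg$fs
  if (fs < 128) stop_named("invalid_fs", "ECG fs must be >= 128 Hz")
  if (signal_duration(ecg) < 10)
    stop_named("short_trial", "ECG must be at least 10 s long")
  bf <- signal::butter(3, c(5, 30) / (fs / 2), type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, ecg$samples))
  sq <- bp^2
  wlen <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- max(0.25 * max(integ), 8 * stats::median(integ))
  if (!is.finite(thr) || thr <= 0)
    stop_named("too_few_peaks", "fewer than 3 peaks found")
  refr <- round(0.2 * fs)
  above <- integ > thr
  # contiguous supra-threshold runs -> one candidate each
  run_start <- which(above & !c(FALSE, above[-length(above)]))
  run_end <- which(above & !c(above[-1], FALSE))
  peaks <- integer(0)
  half <- round(0.05 * fs)
  for (k in seq_along(run_start)) {
    i0 <- max(1L, run_start[k] - half)
    i1 <- min(length(bp), run_end[k] + half)
    p <- i0 + which.max(bp[i0:i1]) - 1L
    if (length(peaks) == 0L || p - peaks[length(peaks)] >= refr) {
      peaks <- c(peaks, p)
    } else if (bp[p] > bp[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- p
    }
  }
  if (length(peaks) < 3L)
    stop_named("too_few_peaks", "fewer than 3 peaks found")
  peaks
}

#' Beat-to-beat (NN) intervals from peak indices
#'
#' Converts successive peak index gaps to intervals in ms and applies the
#' physiological gate: intervals outside (200, 3000) ms are dropped (a
#' message reports how many).
#'
#' @param peaks strictly increasing peak sample indices.
#' @param fs sampling rate in Hz.
#' @return an object of class `nn_series`: list with `nn_ms` and cumulative
#'   `t_ms` (time of the second beat of each interval).
#' @export
nn_from_peaks <- function(peaks, fs) {
  if (is.unsorted(peaks, strictly = TRUE))
    stop_named("invalid_peaks", "peaks must be strictly increasing")
  nn <- diff(peaks) / fs * 1000
  t_ms <- cumsum(nn)
  keep <- nn > 200 & nn < 3000
  if (any(!keep))
    message(sprintf("nn_from_peaks: dropped %d interval(s) outside (200, 3000) ms",
                    sum(!keep)))
  nn <- nn[keep]
  t_ms <- t_ms[keep]
  if (length(nn) < 2L)
    stop_named("too_few_intervals", "fewer than 2 NN intervals survive the gate")
  structure(list(nn_ms = nn, t_ms = t_ms), class = "nn_series")
}

#' Time-domain HRV features
#'
#' Standard statistics of the NN series: mean NN, SDNN (sample SD), RMSSD
#' (root mean square of successive differences), NN50 (count of successive
#' differences exceeding 50 ms) and pNN50 (NN50 as a percentage of the
#' number of successive differences).
#'
#' @param nn an [nn_from_peaks()] result.
#' @return named numeric vector `(nn_mean, sdnn, rmssd, nn50, pnn50)`.
#' @export
ecg_time_features <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  x <- nn$nn_ms
  if (length(x) < 3L)
    stop_named("too_few_intervals", "need at least 3 NN intervals")
  d <- diff(x)
  nn50 <- sum(abs(d) > 50)
  c(nn_mean = mean(x), sdnn = stats::sd(x),
    rmssd = sqrt(mean(d^2)), nn50 = nn50,
    pnn50 = 100 * nn50 / length(d))
}

# Welch power spectral density: Hamming-windowed segments, 50% overlap,
# mean of per-segment periodograms. Returns density per Hz so band means
# are comparable across segment lengths.
welch_psd <- function(x, fs, segment_s) {
  n <- length(x)
  seg <- min(n, round(segment_s * fs))
  step <- max(1L, floor(seg / 2))
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(seg) / (seg + 1))  # Hamming
  norm <- sum(w^2) * fs
  nf <- floor(seg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    xs <- x[s:(s + seg - 1L)]
    xs <- (xs - mean(xs)) * w
    X <- stats::fft(xs)[seq_len(nf)]
    p <- Mod(X)^2 / norm
    # one-sided: double everything except DC (and Nyquist if present)
    p[-1] <- 2 * p[-1]
    if (seg %% 2 == 0) p[nf] <- p[nf] / 2
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1) * fs / seg, psd = acc / length(starts))
}

#' Frequency-domain HRV features
#'
#' The NN tachogram is resampled to 4 Hz by linear interpolation and its
#' Welch PSD computed; `lf_power` is the mean PSD over the LF band
#' (0.04-0.15 Hz), `hf_power` over the HF band (0.15-0.4 Hz), and
#' `lf_hf_ratio` their quotient (reported as `Inf` if the HF power is
#' exactly zero).
#'
#' @param nn an [nn_from_peaks()] result spanning at least 60 s.
#' @param welch_segment_s Welch segment length in seconds (default 64).
#' @return named numeric vector `(lf_power, hf_power, lf_hf_ratio)`; powers
#'   in ms^2/Hz.
#' @export
ecg_freq_features <- function(nn, welch_segment_s = 64) {
  stopifnot(inherits(nn, "nn_series"))
  span_s <- (nn$t_ms[length(nn$t_ms)] - nn$t_ms[1]) / 1000
  # about a minute of beats; the margin admits the edge beats a 60 s
  # recording necessarily loses
  if (span_s < 55)
    stop_named("short_trial", "need about 60 s of beats for spectral HRV")
  fs <- 4
  t_s <- nn$t_ms / 1000
  grid <- seq(t_s[1], t_s[length(t_s)], by = 1 / fs)
  tach <- stats::approx(t_s, nn$nn_ms, xout = grid)$y
  ps <- welch_psd(tach, fs, welch_segment_s)
  lf <- mean(ps$psd[ps$freq >= 0.04 & ps$freq <= 0.15])
  hf <- mean(ps$psd[ps$freq > 0.15 & ps$freq <= 0.4])
  ratio <- if (hf == 0) Inf else lf / hf
  c(lf_power = lf, hf_power = hf, lf_hf_ratio = ratio)
}

## ---- EDA ----------------------------------------------------------------

#' Decompose EDA into tonic and phasic components
#'
#' The skin conductance level (SCL) is a zero-phase 0.05 Hz low-pass of the
#' signal; the phasic component is the residual, so `scl + phasic`
#' reconstructs the input exactly.
#'
#' @param eda a `physio_signal` (sensor `"eda"`), at least 20 s long.
#' @return list with `scl` and `phasic` (both `physio_signal`s).
#' @export
decompose_eda <- function(eda) {
  stopifnot(inherits(eda, "physio_signal"))
  if (signal_duration(eda) < 20)
    stop_named("short_trial", "EDA must be at least 20 s long")
  scl <- zerophase_lowpass(eda$samples, eda$fs, 0.05, order = 3)
  list(scl = physio_signal(scl, eda$fs, "eda"),
       phasic = structure(list(samples = eda$samples - scl, fs = eda$fs,
                               sensor = "eda"), class = "physio_signal"))
}

#' Detect skin-conductance responses on a phasic signal
#'
#' Trough-to-peak detection: local minima and the following local maxima of
#' the phasic signal; an event is kept iff the rise is at least
#' `amp_threshold_us` and the peak stands above the tonic level (phasic
#' zero line) by at least half the threshold -- the latter guards against
#' the rebound artifacts a subtractive tonic/phasic decomposition leaves
#' after a response. Event area is the trapezoidal integral of the phasic
#' signal above the trough level, from onset to recovery (first return to
#' half amplitude, the next onset, or end of signal).
#'
#' @param phasic phasic `physio_signal` from [decompose_eda()].
#' @param amp_threshold_us significance threshold in microsiemens
#'   (default 0.05).
#' @return data frame with columns `onset_s`, `peak_s`, `amplitude_us`,
#'   `area_us_s`, `latency_s` (zero rows if no significant SCR).
#' @export
detect_scrs <- function(phasic, amp_threshold_us = 0.05) {
  stopifnot(inherits(phasic, "physio_signal"))
  x <- phasic$samples
  fs <- phasic$fs
  n <- length(x)
  d <- diff(x)
  # indices where slope turns from <=0 to >0 (troughs) / >0 to <=0 (peaks)
  troughs <- which(d[-1] > 0 & d[-length(d)] <= 0) + 1L
  if (n >= 2 && d[1] > 0) troughs <- c(1L, troughs)
  peaks <- which(d[-1] <= 0 & d[-length(d)] > 0) + 1L
  ev <- list()
  for (tr in troughs) {
    pk <- peaks[peaks > tr]
    if (length(pk) == 0L) next
    pk <- pk[1]
    amp <- x[pk] - x[tr]
    if (amp < amp_threshold_us || x[pk] < amp_threshold_us / 2) next
    nxt <- troughs[troughs > pk]
    lim <- if (length(nxt)) nxt[1] else n
    post <- x[pk:lim]
    rec_rel <- which(post <= x[tr] + amp / 2)
    rec <- if (length(rec_rel)) pk + rec_rel[1] - 1L else lim
    seg <- pmax(x[tr:rec] - x[tr], 0)
    ev[[length(ev) + 1L]] <- data.frame(
      onset_s = (tr - 1) / fs, peak_s = (pk - 1) / fs,
      amplitude_us = amp, area_us_s = trapz_uniform(seg, 1 / fs),
      latency_s = (tr - 1) / fs)
  }
  if (length(ev) == 0L)
    return(data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      amplitude_us = numeric(0), area_us_s = numeric(0),
                      latency_s = numeric(0)))
  do.call(rbind, ev)
}

#' The 12 EDA features of one trial
#'
#' Eight SCL statistics (mean, sample SD, max, min, RMS, mean first
#' difference, mean second difference, and the mean over only the negative
#' first-difference samples, 0 if none) plus four SCR features. The SCR
#' occurrence rate (per minute) is counted on the phasic signal
#' band-limited to the very low frequency band 0-0.1 Hz; the latency of
#' the first significant SCR (trial duration if none) and the sums of
#' event amplitudes and areas are measured on the unfiltered phasic
#' signal, whose trough-to-peak rises are not attenuated by the band
#' limit.
#'
#' @param eda a `physio_signal` (sensor `"eda"`).
#' @param config a [feature_config()].
#' @return named numeric vector of the 12 EDA features.
#' @export
eda_features <- function(eda, config = feature_config()) {
  comp <- decompose_eda(eda)
  scl <- comp$scl$samples
  d1 <- diff(scl)
  d2 <- diff(scl, differences = 2)
  neg <- d1[d1 < 0]
  ev <- detect_scrs(comp$phasic, config$scr_threshold_us)
  ev_rate <- if (config$scr_vlf_band) {
    vlf <- structure(list(
      samples = zerophase_lowpass(comp$phasic$samples, comp$phasic$fs, 0.1),
      fs = comp$phasic$fs, sensor = "eda"), class = "physio_signal")
    detect_scrs(vlf, config$scr_threshold_us)
  } else ev
  dur <- signal_duration(eda)
  c(scl_mean = mean(scl), scl_std = stats::sd(scl), scl_max = max(scl),
    scl_min = min(scl), scl_rms = sqrt(mean(scl^2)),
    scl_d1_mean = mean(d1), scl_d2_mean = mean(d2),
    scl_negslope_mean = if (length(neg)) mean(neg) else 0,
    scr_rate_vlf = nrow(ev_rate) / dur * 60,
    scr_first_latency = if (nrow(ev)) ev$onset_s[1] else dur,
    scr_amp_sum = sum(ev$amplitude_us), scr_area_sum = sum(ev$area_us_s))
}

## ---- Skin temperature ---------------------------------------------------

#' Skin-temperature statistics
#'
#' Mean, max and sample SD; in extended mode also min and the mean first
#' difference (per sample).
#'
#' @param st a `physio_signal` (sensor `"st"`).
#' @param config a [feature_config()].
#' @return named numeric vector of 3 or 5 features.
#' @export
st_features <- function(st, config = feature_config()) {
  stopifnot(inherits(st, "physio_signal"))
  x <- st$samples
  out <- c(st_mean = mean(x), st_max = max(x), st_std = stats::sd(x))
  if (config$st_extended)
    out <- c(out, st_min = min(x), st_d1_mean = mean(diff(x)))
  out
}

## ---- Full vector --------------------------------------------------------

#' Extract the full feature vector of one trial
#'
#' Concatenates, in fixed order, the 12 EDA features, the 8 ECG (HRV)
#' features and the skin-temperature statistics (3 by default, 5 in
#' extended mode). Any sub-extractor failure fails the trial with its own
#' error.
#'
#' @param trial a `trial_recording`.
#' @param config a [feature_config()].
#' @return named numeric vector of length 23 or 25.
#' @export
extract_features <- function(trial, config = feature_config()) {
  stopifnot(inherits(trial, "trial_recording"))
  peaks <- detect_r_peaks(trial$ecg)
  nn <- nn_from_peaks(peaks, trial$ecg$fs)
  out <- c(eda_features(trial$eda, config),
           ecg_time_features(nn),
           ecg_freq_features(nn, config$welch_segment_s),
           st_features(trial$st, config))
  stopifnot(identical(names(out), feature_names(config)))
  out
}

#' Extract a feature table for a list of trials
#'
#' @param trials list of `trial_recording` objects.
#' @param config a [feature_config()].
#' @return data frame with `subject_id`, `trial_id`, one column per
#'   feature, `valence_raw`, `arousal_raw` and `class_index`.
#' @export
extract_features_dataset <- function(trials, config = feature_config()) {
  rows <- lapply(trials, function(tr) {
    fv <- extract_features(tr, config)
    cbind(data.frame(subject_id = tr$subject_id, trial_id = tr$trial_id),
          as.data.frame(t(fv)),
          data.frame(valence_raw = tr$label$valence_raw,
                     arousal_raw = tr$label$arousal_raw,
                     class_index = tr$label$class_index))
  })
  do.call(rbind, rows)
}

#' Split a feature table into its feature matrix and metadata
#' @param features a data frame from [extract_features_dataset()].
#' @return list with `x` (numeric matrix, feature columns only),
#'   `subjects`, `classes` (integer 0-3 or NULL if absent).
#' @export
feature_matrix <- function(features) {
  meta <- c("subject_id", "trial_id", "valence_raw", "arousal_raw",
            "class_index")
  fcols <- setdiff(names(features), meta)
  list(x = as.matrix(features[, fcols, drop = FALSE]),
       subjects = features$subject_id,
       classes = if ("class_index" %in% names(features))
         as.integer(features$class_index) else NULL)
}
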
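# Shared fixture builders (everything generated in code).

lab_hh <- function() emotion_label(7, 8)  # HV-HA
lab_ll <- function() emotion_label(3, 2)  # LV-LA
lab_lh <- function() emotion_label(3, 8)  # LV-HA

zero_effect <- function() {
  structure(list(hr_offset_bpm = 0, eda_gain = 1, eda_baseline_us = 5,
                 st_baseline_c = 32.5, rng_seed = 0L),
            class = "subject_effect")
}

# Zeroed 1-cell templates with a hook to set A/B/bias, for closed-form
# integration checks.
toy_templates <- function(n = 1L, m = 1L, A = matrix(0, n, n),
                          B = matrix(0, n, m), bias = rep(0, n)) {
  structure(list(A = A, B = B, bias = bias, n = n, m = m,
                 sensor = "ecg", seed = 0L), class = "cnn_templates")
}

# Biexponential SCR bump of given amplitude, placed at onset_s in a flat
# signal of the given duration (4 Hz).
bump_signal <- function(onsets_s, amps, duration_s, baseline = 5, fs = 4) {
  ker <- physioemo:::scr_kernel(fs)
  x <- numeric(round(duration_s * fs))
  for (j in seq_along(onsets_s)) {
    i0 <- round(onsets_s[j] * fs) + 1L
    idx <- i0:min(length(x), i0 + length(ker) - 1L)
    x[idx] <- x[idx] + amps[j] * ker[seq_along(idx)]
  }
  physio_signal(baseline + x, fs, "eda")
}

# Linearly separable 4-class feature table: class means far apart on a few
# features, small within-class noise, balanced over subjects.
separable_features <- function(n_per_class = 16, n_subjects = 4, seed = 1) {
  fn <- feature_names(feature_config())
  set.seed(seed)
  rows <- list()
  k <- 0
  for (cls in 0:3) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      v <- stats::setNames(rnorm(length(fn), 0, 0.2), fn)
      v["nn_mean"] <- 700 + 100 * (cls %% 2) + rnorm(1, 0, 5)
      v["scr_rate_vlf"] <- 2 + 4 * (cls %% 2) + rnorm(1, 0, 0.3)
      v["st_mean"] <- 31 + 2 * (cls %/% 2) + rnorm(1, 0, 0.1)
      v["scl_mean"] <- 4 + 2 * (cls %/% 2) + rnorm(1, 0, 0.2)
      rows[[k]] <- cbind(
        data.frame(subject_id = sprintf("S%02d", (k %% n_subjects) + 1),
                   trial_id = sprintf("T%03d", k)),
        as.data.frame(t(v)),
        data.frame(valence_raw = if (cls >= 2) 7L else 3L,
                   arousal_raw = if (cls %% 2 == 1) 7L else 3L,
                   class_index = cls))
    }
  }
  do.call(rbind, rows)
}

# Four directionally separated 2-d Gaussian blobs (for clustering tests).
four_blobs <- function(n_per = 100, sd = 0.5, data_seed = 1) {
  ctr <- rbind(c(10, 0), c(0, 10), c(-10, 0), c(0, -10))
  set.seed(data_seed)
  do.call(rbind, lapply(1:4, function(j)
    matrix(rnorm(n_per * 2, sd = sd), ncol = 2) + rep(ctr[j, ], each = n_per)))
}
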
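test_that("R-peak detection recovers constructed and generated beats", {
  ecg <- gen_ecg(rep(1000, 11), fs = 256, noise_sd = 0)
  pk <- detect_r_peaks(ecg)
  expect_true(all(abs(pk[1:3] - c(257, 513, 769)) <= 1))

  # generated trials: >= 99% of injected beats within 2 samples, 30 seeds
  hits <- misses <- 0
  for (s in 1:30) {
    lab <- if (s %% 2) lab_hh() else lab_ll()
    eff <- gen_subject_effect(s)
    rr <- gen_rr_series(lab, eff, 60, s)
    ecg <- gen_ecg(rr, 256, duration_s = 60, seed = s)
    inj <- round(attr(ecg, "peak_times_s") * 256) + 1
    pk <- detect_r_peaks(ecg)
    d <- vapply(inj, function(i) min(abs(pk - i)), 0)
    hits <- hits + sum(d <= 2); misses <- misses + sum(d > 2)
  }
  expect_gte(hits / (hits + misses), 0.99)

  flat <- physio_signal(rep(0, 256 * 15), 256, "ecg")
  expect_error(detect_r_peaks(flat), class = "too_few_peaks")
})

test_that("NN intervals follow from peak gaps with the physiological gate", {
  nn <- nn_from_peaks(c(0, 256, 512) + 1, 256)
  expect_equal(nn$nn_ms, c(1000, 1000))
  nn2 <- nn_from_peaks(c(1, 206, 416), 256)
  expect_equal(nn2$nn_ms, c(800.78125, 820.3125), tolerance = 1e-10)
  # a 100 ms gap is dropped and reported
  expect_message(nn3 <- nn_from_peaks(c(0, 256, 282, 538, 794) + 1, 256),
                 "dropped 1")
  expect_length(nn3$nn_ms, 3)
  expect_error(nn_from_peaks(c(1, 26), 256), class = "too_few_intervals")
})

test_that("time-domain HRV features match hand-computed values", {
  nn <- structure(list(nn_ms = c(800, 810, 790, 805),
                       t_ms = cumsum(c(800, 810, 790, 805))),
                  class = "nn_series")
  f <- ecg_time_features(nn)
  expect_equal(f[["nn_mean"]], 801.25)
  expect_equal(f[["sdnn"]], 8.539, tolerance = 1e-3)
  expect_equal(f[["rmssd"]], 15.546, tolerance = 1e-3)
  expect_equal(f[["nn50"]], 0)
  expect_equal(f[["pnn50"]], 0)

  nn2 <- structure(list(nn_ms = c(800, 860, 805), t_ms = cumsum(c(800, 860, 805))),
                   class = "nn_series")
  f2 <- ecg_time_features(nn2)
  expect_equal(f2[["nn50"]], 2)
  expect_equal(f2[["pnn50"]], 100)

  cst <- structure(list(nn_ms = rep(800, 10), t_ms = cumsum(rep(800, 10))),
                   class = "nn_series")
  f3 <- ecg_time_features(cst)
  expect_equal(unname(f3[c("sdnn", "rmssd", "nn50")]), c(0, 0, 0))
})

test_that("spectral HRV places tachogram tones in the right band", {
  tone_nn <- function(f_hz, dur_s = 300) {
    t <- 0; nn <- numeric(0)
    while (t < dur_s * 1000) {
      v <- 1000 + 50 * sin(2 * pi * f_hz * t / 1000)
      nn <- c(nn, v); t <- t + v
    }
    structure(list(nn_ms = nn, t_ms = cumsum(nn)), class = "nn_series")
  }
  f_lf <- ecg_freq_features(tone_nn(0.10))
  expect_gt(f_lf[["lf_power"]], 10 * f_lf[["hf_power"]])
  f_hf <- ecg_freq_features(tone_nn(0.25))
  expect_gt(f_hf[["hf_power"]], 10 * f_hf[["lf_power"]])

  # white-jitter tachogram: LF/HF ratio stays near the flat-spectrum value
  ratios <- sapply(1:30, function(s) {
    set.seed(s)
    nn <- 1000 + rnorm(360, 0, 30)
    ecg_freq_features(structure(list(nn_ms = nn, t_ms = cumsum(nn)),
                                class = "nn_series"))[["lf_hf_ratio"]]
  })
  expect_true(all(ratios > 0.2 & ratios < 5))
})

test_that("EDA decomposition is exact and splits tonic from phasic energy", {
  cst <- physio_signal(rep(5, 240), 4, "eda")
  comp <- decompose_eda(cst)
  expect_lt(max(abs(comp$phasic$samples)), 1e-6)
  expect_lt(max(abs(comp$scl$samples - 5)), 1e-6)
  expect_equal(comp$scl$samples + comp$phasic$samples, cst$samples,
               tolerance = 1e-12)

  # ramp + one bump: the tonic ramp stays in SCL, the bump's
  # trough-to-peak rise stays in the phasic component
  n <- 480
  ramp <- 4 + seq(0, 1, length.out = n)
  comp_ramp <- decompose_eda(physio_signal(ramp, 4, "eda"))
  expect_lt(max(abs(comp_ramp$phasic$samples)), 0.01)
  bump <- bump_signal(30, 0.8, 120, baseline = 0)$samples
  x <- physio_signal(ramp + bump, 4, "eda")
  comp2 <- decompose_eda(x)
  ev <- detect_scrs(comp2$phasic)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$amplitude_us - 0.8) / 0.8, 0.15)
  expect_error(decompose_eda(physio_signal(rep(5, 20), 4, "eda")),
               class = "short_trial")
})

test_that("SCR detection keeps supra-threshold trough-to-peak events only", {
  flat <- physio_signal(rep(0, 400), 4, "eda")
  flat$sensor <- "eda"
  expect_identical(nrow(detect_scrs(flat)), 0L)

  one <- decompose_eda(bump_signal(30, 0.5, 120))$phasic
  ev <- detect_scrs(one)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$amplitude_us - 0.5), 0.05)
  expect_gt(ev$peak_s, ev$onset_s)

  tiny <- decompose_eda(bump_signal(30, 0.01, 120))$phasic
  expect_identical(nrow(detect_scrs(tiny, 0.05)), 0L)
})

test_that("EDA feature vector handles degenerate and constructed inputs", {
  cst <- physio_signal(rep(5, 240), 4, "eda")
  f <- eda_features(cst)
  expect_equal(f[["scl_mean"]], 5, tolerance = 1e-9)
  expect_equal(f[["scl_std"]], 0, tolerance = 1e-6)
  expect_equal(f[["scl_rms"]], 5, tolerance = 1e-9)
  expect_equal(f[["scl_negslope_mean"]], 0)
  expect_equal(unname(f[c("scr_rate_vlf", "scr_first_latency",
                          "scr_amp_sum", "scr_area_sum")]),
               c(0, 60, 0, 0))

  # strictly decreasing ramp: slope features track the per-sample slope
  ramp <- physio_signal(7 - 0.01 * (0:479), 4, "eda")
  fr <- eda_features(ramp)
  expect_equal(fr[["scl_d1_mean"]], -0.01, tolerance = 1e-3)
  expect_equal(fr[["scl_negslope_mean"]], -0.01, tolerance = 1e-3)

  # three injected bumps in 60 s
  x <- bump_signal(c(10, 30, 45), rep(0.5, 3), 60)
  fb <- eda_features(x)
  expect_equal(fb[["scr_rate_vlf"]], 3, tolerance = 1e-9)
  expect_lt(abs(fb[["scr_amp_sum"]] - 1.5) / 1.5, 0.15)
  expect_equal(fb[["scr_first_latency"]], 10, tolerance = 0.5)
})

test_that("EDA features are scale-equivariant in the signal gain", {
  eda <- gen_eda(lab_hh(), zero_effect(), 120, 4, 31)
  g <- 2.5
  scaled <- physio_signal(g * eda$samples, 4, "eda")
  f1 <- eda_features(eda, feature_config(scr_threshold_us = 0.05))
  f2 <- eda_features(scaled, feature_config(scr_threshold_us = g * 0.05))
  lin <- c("scl_mean", "scl_std", "scl_max", "scl_min", "scl_rms",
           "scr_amp_sum", "scr_area_sum")
  expect_equal(unname(f2[lin]), unname(g * f1[lin]), tolerance = 1e-8)
  expect_equal(f2[["scr_rate_vlf"]], f1[["scr_rate_vlf"]])
})

test_that("skin-temperature statistics match hand arithmetic", {
  cst <- physio_signal(rep(33, 100), 4, "st")
  expect_equal(unname(st_features(cst, feature_config(st_extended = FALSE))),
               c(33, 33, 0))
  x <- physio_signal(c(32, 33, 34), 4, "st")
  expect_equal(unname(st_features(x, feature_config(st_extended = FALSE))),
               c(33, 34, 1))
  ext <- st_features(x, feature_config(st_extended = TRUE))
  expect_equal(ext[["st_min"]], 32)
  expect_equal(ext[["st_d1_mean"]], 1)
})

test_that("full vectors have the documented length, order and determinism", {
  tr <- gen_trial("S01", "T01", lab_hh(), gen_subject_effect(3), 120, seed = 7)
  fv <- extract_features(tr)
  expect_length(fv, 25)
  expect_identical(names(fv), feature_names(feature_config()))
  fv23 <- extract_features(tr, feature_config(st_extended = FALSE))
  expect_length(fv23, 23)
  expect_identical(extract_features(tr), fv)
})

test_that("features respond in the generator's designed direction and stay finite", {
  trials <- gen_dataset(4, 8, 90, seed = 13)
  ft <- extract_features_dataset(trials)
  expect_true(all(vapply(ft[feature_names(feature_config())], function(col)
    all(is.finite(col)), TRUE)))
  hi <- ft$arousal_raw > 5
  expect_gt(mean(ft$scr_rate_vlf[hi]), mean(ft$scr_rate_vlf[!hi]))
  expect_lt(mean(ft$rmssd[hi]), mean(ft$rmssd[!hi]))
})
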
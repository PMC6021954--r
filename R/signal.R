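#' Construct a uniformly sampled physiological signal
#'
#' Lightweight container for one channel: a numeric sample vector, its
#' sampling rate, and the sensor it came from. Units are the sensor's
#' native units (ECG mV, EDA microsiemens, skin temperature degrees C).
#'
#' @param samples numeric vector of samples (finite).
#' @param fs sampling rate in Hz (> 0).
#' @param sensor one of `"ecg"`, `"eda"`, `"st"`.
#' @return An object of class `physio_signal`.
#' @export
physio_signal <- function(samples, fs, sensor = c("ecg", "eda", "st")) {
  sensor <- match.arg(sensor)
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_named("invalid_fs", "fs must be a single positive number")
  if (length(samples) == 0L)
    stop_named("empty_signal", "signal has no samples")
  if (!all(is.finite(samples)))
    stop_named("nonfinite_signal", "signal contains non-finite samples")
  structure(list(samples = samples, fs = fs, sensor = sensor),
            class = "physio_signal")
}

#' @export
print.physio_signal <- function(x, ...) {
  cat(sprintf("<physio_signal> sensor=%s, fs=%g Hz, n=%d (%.1f s)\n",
              x$sensor, x$fs, length(x$samples), signal_duration(x)))
  invisible(x)
}

#' Duration of a signal in seconds
#' @param x a `physio_signal`.
#' @return duration in seconds (`n / fs`).
#' @export
signal_duration <- function(x) length(x$samples) / x$fs

#' Resample a signal to a target rate
#'
#' Standard preprocessing brings every channel to a fixed rate (256 Hz ECG,
#' 4 Hz EDA and skin temperature). Linear interpolation onto the target
#' grid; physiological channels are smooth relative to both grids, so no
#' anti-alias stage is applied. A signal already at the target rate is
#' returned unchanged.
#'
#' @param x a `physio_signal`.
#' @param target_fs target sampling rate in Hz.
#' @return a `physio_signal` at `target_fs`; duration preserved within one
#'   sample period.
#' @export
resample_signal <- function(x, target_fs) {
  stopifnot(inherits(x, "physio_signal"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop_named("invalid_fs", "target_fs must be positive")
  if (isTRUE(all.equal(x$fs, target_fs))) return(x)
  n_out <- round(length(x$samples) * target_fs / x$fs)
  t_in <- (seq_along(x$samples) - 1) / x$fs
  t_out <- (seq_len(n_out) - 1) / target_fs
  y <- stats::approx(t_in, x$samples, xout = pmin(t_out, max(t_in)),
                     rule = 2)$y
  physio_signal(y, target_fs, x$sensor)
}

#' Read a two-column signal CSV
#'
#' Parses the `time_s,value` schema written by [write_trial()]. The sampling
#' rate is inferred from the median sample spacing and is validated to be
#' uniform within 1%.
#'
#' @param path CSV file path.
#' @param sensor sensor tag for the returned signal.
#' @return a `physio_signal`.
#' @export
read_signal_csv <- function(path, sensor = c("ecg", "eda", "st")) {
  sensor <- match.arg(sensor)
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop_named("empty_file", "empty signal file: %s", path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop_named("bad_schema", "expected columns time_s,value in %s", path)
  dt <- diff(df$time_s)
  if (any(dt <= 0))
    stop_named("non_monotone_time", "non-monotone time in %s", path)
  med <- stats::median(dt)
  if (any(abs(dt - med) > 0.01 * med))
    stop_named("irregular_sampling", "irregular sampling in %s", path)
  physio_signal(df$value, 1 / med, sensor)
}

#' Write a signal to a two-column CSV
#' @param x a `physio_signal`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  t <- (seq_along(x$samples) - 1) / x$fs
  utils::write.csv(data.frame(time_s = t, value = x$samples), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
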
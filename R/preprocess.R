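#' EMG recording container
#'
#' A light S3 record for a continuous single-channel EMG series: samples in
#' microvolts at a fixed sampling rate, an optional reference to the
#' session schedule, and a channel label.
#'
#' @param samples Numeric vector of microvolt samples; must be finite.
#' @param sampling_rate Sampling rate in Hz (only 1000 is supported by the
#'   processing chain).
#' @param events Optional `session_schedule`.
#' @param channel_label Channel name.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, sampling_rate = 1000, events = NULL,
                          channel_label = "EMG_OO_L") {
  if (!all(is.finite(samples))) {
    abort("EMG samples must be finite", class = "startlekit_config_error")
  }
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         events = events, channel_label = channel_label),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s: %d samples @ %g Hz (%.1f s)\n",
              x$channel_label, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Offline EMG processing chain
#'
#' Applies, in order: 65 Hz high-pass, full-wave rectification, 40-ms
#' centered moving average, 2 Hz high-pass (slow-drift removal), then
#' clamps the slightly negative residuals left by the final high-pass at
#' zero so the result is a non-negative startle response curve. Both
#' high-pass stages are zero-phase with the squared magnitude response of
#' a 4th-order Butterworth (the forward-backward equivalent), so response
#' latencies are not shifted. The amplifier's 1-200 Hz acquisition
#' bandpass is treated as a property of the input data and is not
#' re-applied here.
#'
#' @param recording An [emg_recording()] at 1000 Hz.
#' @param highpass_hz Cutoff of the first high-pass stage.
#' @param smooth_ms Moving-average window in milliseconds.
#' @param drift_hz Cutoff of the final drift-removal high-pass.
#' @param filter_order Butterworth order of each high-pass stage.
#' @param drift_after_smoothing Apply drift removal after the smoothing
#'   stage (the documented chain order). `FALSE` moves it before
#'   rectification, for sensitivity analyses.
#' @param clamp_negative Clamp post-drift-removal negatives at zero.
#' @return An object of class `processed_signal`: `samples` (non-negative
#'   microvolts, same length as the input), `sampling_rate`, `events`,
#'   `artifact_mask` (initially all `FALSE`; see [mark_artifacts()]) and a
#'   `processing_log` of applied steps.
#' @export
preprocess_emg <- function(recording,
                           highpass_hz = 65,
                           smooth_ms = 40,
                           drift_hz = 2,
                           filter_order = 4,
                           drift_after_smoothing = TRUE,
                           clamp_negative = TRUE) {
  if (!inherits(recording, "emg_recording")) {
    abort("recording must be an emg_recording", class = "startlekit_config_error")
  }
  fs <- recording$sampling_rate
  if (fs != 1000) {
    abort("only a 1000 Hz sampling rate is supported",
          class = "startlekit_rate_error")
  }
  x <- recording$samples
  log <- character(0)
  if (length(x) > 1 && stats::sd(x) > 0) {
    if (!drift_after_smoothing) {
      x <- zero_phase_highpass(x, fs, drift_hz, filter_order)
      log <- c(log, sprintf("highpass %g Hz (order %d, zero-phase)", drift_hz, filter_order))
    }
    x <- zero_phase_highpass(x, fs, highpass_hz, filter_order)
    log <- c(log, sprintf("highpass %g Hz (order %d, zero-phase)", highpass_hz, filter_order))
    x <- abs(x)
    log <- c(log, "full-wave rectification")
    x <- moving_average(x, as.integer(round(smooth_ms * fs / 1000)))
    log <- c(log, sprintf("moving average %g ms", smooth_ms))
    if (drift_after_smoothing) {
      x <- zero_phase_highpass(x, fs, drift_hz, filter_order)
      log <- c(log, sprintf("highpass %g Hz (order %d, zero-phase)", drift_hz, filter_order))
    }
    if (clamp_negative) {
      x <- pmax(x, 0)
      log <- c(log, "negative residuals clamped at 0")
    }
  } else {
    # all-constant input passes through to all-zero output
    x <- numeric(length(x))
    log <- "constant input: all-zero output"
  }
  structure(
    list(samples = x, sampling_rate = fs, events = recording$events,
         raw_samples = recording$samples,
         artifact_mask = logical(length(x)), processing_log = log),
    class = "processed_signal"
  )
}

#' @export
print.processed_signal <- function(x, ...) {
  cat(sprintf("<processed_signal> %d samples @ %g Hz, %d masked\n",
              length(x$samples), x$sampling_rate, sum(x$artifact_mask)))
  for (s in x$processing_log) cat("  -", s, "\n")
  invisible(x)
}

#' Automated electrode-artifact marking
#'
#' Automated surrogate for visual artifact rejection, targeting
#' step/drift electrode transients. Blink bursts are zero-mean 30-300 Hz
#' events and vanish in a 100-ms moving average of the raw signal, while
#' electrode steps and drifts survive it at nearly full amplitude, so the
#' rules operate on that slow component: samples whose slow component
#' exceeds `drift_uv` (or whose raw amplitude exceeds `ceiling_uv`, or
#' whose slow-component derivative exceeds `slope_uv_per_ms`) are
#' flagged, and flags are dilated by `dilate_ms` on both sides. Trials
#' whose baseline or response window overlaps the mask are invalidated by
#' the scoring stage. Any rule is disabled by setting it to `Inf`.
#'
#' @param signal A `processed_signal` (carries the raw samples).
#' @param drift_uv Absolute ceiling on the 100-ms-averaged raw signal;
#'   the primary step/drift detector.
#' @param ceiling_uv Absolute raw-amplitude ceiling (hard clipping).
#' @param slope_uv_per_ms Derivative ceiling on the slow component.
#' @param dilate_ms Mask dilation on each side of a flagged sample.
#' @param slow_ms Averaging window defining the slow component.
#' @return The `processed_signal` with its `artifact_mask` replaced.
#' @export
mark_artifacts <- function(signal, drift_uv = 50, ceiling_uv = 1000,
                           slope_uv_per_ms = Inf, dilate_ms = 50,
                           slow_ms = 100) {
  raw <- signal$raw_samples %||% signal$samples
  fs <- signal$sampling_rate
  n <- length(raw)
  bad <- logical(n)
  if (is.finite(ceiling_uv)) bad <- abs(raw) > ceiling_uv
  if ((is.finite(drift_uv) || is.finite(slope_uv_per_ms)) && n > 1) {
    slow <- moving_average(raw, as.integer(round(slow_ms * fs / 1000)))
    if (is.finite(drift_uv)) bad <- bad | abs(slow) > drift_uv
    if (is.finite(slope_uv_per_ms)) {
      bad[-1] <- bad[-1] | abs(diff(slow)) * fs / 1000 > slope_uv_per_ms
    }
  }
  if (any(bad)) {
    r <- as.integer(round(dilate_ms * fs / 1000))
    idx <- which(bad)
    lo <- pmax(idx - r, 1L)
    hi <- pmin(idx + r, n)
    mask <- logical(n)
    for (k in seq_along(idx)) mask[lo[k]:hi[k]] <- TRUE
  } else {
    mask <- logical(n)
  }
  signal$artifact_mask <- mask
  signal$processing_log <- c(
    signal$processing_log,
    sprintf("artifact mask: drift %g uV, ceiling %g uV, slope %g uV/ms, %d samples",
            drift_uv, ceiling_uv, slope_uv_per_ms, sum(mask))
  )
  signal
}

#' Write / read a continuous EMG signal as headered TSV
#'
#' Plain-text signal interchange: a two-column tab-separated file
#' (`time_s`, `amplitude_uv`) preceded by header lines
#' `# sampling_rate_hz: <rate>` and `# channel: <label>`.
#'
#' @param recording An [emg_recording()].
#' @param path File path.
#' @param digits Significant digits written (default full precision).
#' @return `write_signal_tsv()` returns `path` invisibly;
#'   `read_signal_tsv()` returns an [emg_recording()] (without events).
#' @export
write_signal_tsv <- function(recording, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %g", recording$sampling_rate), con)
  writeLines(sprintf("# channel: %s", recording$channel_label), con)
  writeLines("time_s\tamplitude_uv", con)
  t <- (seq_along(recording$samples) - 1) / recording$sampling_rate
  writeLines(paste(format(t, trim = TRUE, scientific = FALSE),
                   formatC(recording$samples, digits = digits, format = "g"),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_signal_tsv
#' @export
read_signal_tsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  m <- regmatches(hdr[1], regexec("sampling_rate_hz:\\s*([0-9.]+)", hdr[1]))[[1]]
  if (length(m) < 2) {
    abort("missing 'sampling_rate_hz' header line", class = "startlekit_parse_error")
  }
  rate <- as.numeric(m[2])
  lab <- sub("^#\\s*channel:\\s*", "", hdr[2])
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = "dd")
  if (!identical(names(d), c("time_s", "amplitude_uv"))) {
    abort("expected columns time_s and amplitude_uv", class = "startlekit_parse_error")
  }
  emg_recording(d$amplitude_uv, sampling_rate = rate, channel_label = lab)
}
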
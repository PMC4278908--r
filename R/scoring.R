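#' Response-window configuration
#'
#' Parameters of startle-response detection: a 500-ms pre-probe baseline,
#' a validity threshold of `threshold_k` baseline SDs above the baseline
#' mean, a 20-110 ms post-probe latency window inside which the response
#' curve must first exceed and then fall back below the threshold, and a
#' fixed 40-90 ms target window over which the amplitude is taken.
#'
#' @param baseline_ms Baseline length before probe onset (ms).
#' @param threshold_k Baseline-SD multiplier of the validity threshold.
#' @param validity_window_ms Two-element onset/return latency window (ms
#'   after probe onset).
#' @param amplitude_window_ms Two-element fixed target window (ms after
#'   probe onset).
#' @return A list of class `response_window_config`.
#' @export
response_window_config <- function(baseline_ms = 500,
                                   threshold_k = 3,
                                   validity_window_ms = c(20, 110),
                                   amplitude_window_ms = c(40, 90)) {
  if (amplitude_window_ms[1] < validity_window_ms[1] - 1e-9 ||
      baseline_ms <= 0 || threshold_k < 0) {
    abort("invalid response-window configuration",
          class = "startlekit_config_error")
  }
  structure(
    list(baseline_ms = baseline_ms, threshold_k = threshold_k,
         validity_window_ms = validity_window_ms,
         amplitude_window_ms = amplitude_window_ms),
    class = "response_window_config"
  )
}

#' Detect and validate one startle response
#'
#' Implements the trial-level response definition. The threshold is
#' `baseline_mean + threshold_k * baseline_sd`, computed on the processed
#' signal over the `baseline_ms` before probe onset. The response is valid
#' if the curve first strictly exceeds the threshold inside the
#' 20-110 ms post-probe latency window and falls back below it by the end
#' of that window. The amplitude is the maximum of the processed signal in
#' the fixed 40-90 ms target window minus the baseline mean, floored at
#' zero. Degenerate baselines (SD = 0) require the curve to strictly
#' exceed the baseline mean; the return-below condition is waived there
#' because the threshold band has zero width. Trials whose baseline or
#' latency window overlaps the artifact mask are invalid with reason
#' `artifact`.
#'
#' @param signal A `processed_signal`.
#' @param probe_onset_s Probe onset in session seconds.
#' @param config A [response_window_config()].
#' @return One-row tibble: `probe_onset_s`, `valid`, `invalid_reason`
#'   (`no_crossing`, `late_onset`, `no_return`, `artifact` or `none`),
#'   `onset_latency_ms`, `amplitude`, `baseline_mean`, `baseline_sd`.
#' @export
detect_startle_response <- function(signal, probe_onset_s,
                                    config = response_window_config()) {
  fs <- signal$sampling_rate
  x <- signal$samples
  p <- as.integer(round(probe_onset_s * fs)) + 1L # sample index of probe onset
  nb <- as.integer(round(config$baseline_ms * fs / 1000))
  if (p - nb < 1L) {
    abort("probe too close to recording start for a full baseline",
          class = "startlekit_window_error")
  }
  vw <- as.integer(round(config$validity_window_ms * fs / 1000))
  aw <- as.integer(round(config$amplitude_window_ms * fs / 1000))
  if (p + vw[2] > length(x) || p + aw[2] > length(x)) {
    abort("probe too close to recording end for the response windows",
          class = "startlekit_window_error")
  }
  base_idx <- (p - nb):(p - 1L)
  val_idx <- (p + vw[1]):(p + vw[2])
  amp_idx <- (p + aw[1]):(p + aw[2])

  res <- tibble(
    probe_onset_s = probe_onset_s, valid = FALSE, invalid_reason = "none",
    onset_latency_ms = NA_real_, amplitude = NA_real_,
    baseline_mean = NA_real_, baseline_sd = NA_real_
  )
  if (any(signal$artifact_mask[c(base_idx, val_idx, amp_idx)])) {
    res$invalid_reason <- "artifact"
    return(res)
  }
  bm <- mean(x[base_idx])
  bs <- stats::sd(x[base_idx])
  res$baseline_mean <- bm
  res$baseline_sd <- bs
  thr <- bm + config$threshold_k * bs

  seg <- x[val_idx]
  above <- seg > thr
  if (!any(above)) {
    # check whether a crossing exists later (outside the latency window):
    # that is a late onset rather than no response at all
    post <- x[(p + vw[2] + 1L):min(p + 4L * vw[2], length(x))]
    res$invalid_reason <- if (length(post) > 0 && any(post > thr) && bs > 0) {
      "late_onset"
    } else if (length(post) > 0 && bs == 0 && any(post > bm)) {
      "late_onset"
    } else {
      "no_crossing"
    }
    return(res)
  }
  first <- which(above)[1L]
  onset_ms <- (val_idx[first] - p) * 1000 / fs
  returned <- first < length(seg) && any(!above[(first + 1L):length(seg)])
  if (!returned && bs > 0) {
    res$invalid_reason <- "no_return"
    res$onset_latency_ms <- onset_ms
    return(res)
  }
  res$valid <- TRUE
  res$onset_latency_ms <- onset_ms
  res$amplitude <- max(max(x[amp_idx]) - bm, 0)
  res
}

#' Detect responses for every probe of a session
#'
#' Runs [detect_startle_response()] over all startle probes of the
#' schedule attached to the signal (habituation tones, probed CS trials
#' and ITI probes).
#'
#' @param signal A `processed_signal` carrying its `session_schedule`.
#' @param config A [response_window_config()].
#' @param schedule Optional schedule overriding `signal$events`.
#' @return A tibble with one row per probe: schedule fields (`phase`,
#'   `trial_type`, `probe_ordinal`) plus the detection fields.
#' @export
detect_responses <- function(signal, config = response_window_config(),
                             schedule = NULL) {
  schedule <- schedule %||% signal$events
  if (is.null(schedule)) {
    abort("no schedule attached to the signal", class = "startlekit_config_error")
  }
  probes <- probe_events(schedule)
  det <- purrr::map(probes$probe_onset,
                    \(t) detect_startle_response(signal, t, config))
  dplyr::bind_cols(
    dplyr::select(probes, "phase", "trial_type", "probe_ordinal"),
    dplyr::bind_rows(det)
  )
}

#' Per-participant condition means and ITI-proportional scores
#'
#' Averages valid response amplitudes per (phase, condition) cell, takes
#' the mean ITI startle amplitude of the acquisition phase as the
#' reference value, and expresses each CS cell as a proportion of it
#' (for both acquisition and extinction, since ITI startle habituates
#' across the session and acquisition ITIs show minimal habituation).
#' The differential (strength of conditioning) is proportional CS+ minus
#' proportional CS- per phase. Habituation-phase probes contribute to no
#' score cell. Invalid trials are excluded, never zero-filled; a
#' participant with no valid acquisition ITI probe is flagged unscorable
#' (`scorable = FALSE`, proportional scores `NA`).
#'
#' @param responses Tibble from [detect_responses()] covering all probed
#'   trials of one participant.
#' @param id Participant identifier carried into the output.
#' @return A one-row tibble: `id`, `scorable`, `iti_reference`, per-cell
#'   `n_valid_*` and `mean_*`, proportional scores `acq_prop_csp`,
#'   `acq_prop_csm`, `ext_prop_csp`, `ext_prop_csm` and differentials
#'   `acq_differential`, `ext_differential` (differentials are `NA` unless
#'   both CS cells of the phase have at least one valid trial).
#' @export
score_participant <- function(responses, id = "S001") {
  cell <- function(ph, tt) {
    r <- responses[responses$phase == ph & responses$trial_type == tt &
                     responses$valid, ]
    list(n = nrow(r), mean = if (nrow(r) > 0) mean(r$amplitude) else NA_real_)
  }
  acq_iti <- cell("acquisition", "ITIprobe")
  acq_p <- cell("acquisition", "CSplus")
  acq_m <- cell("acquisition", "CSminus")
  ext_p <- cell("extinction", "CSplus")
  ext_m <- cell("extinction", "CSminus")
  ext_iti <- cell("extinction", "ITIprobe")
  scorable <- acq_iti$n > 0 && is.finite(acq_iti$mean) && acq_iti$mean > 0
  ref <- if (scorable) acq_iti$mean else NA_real_
  prop <- function(cl) if (scorable && cl$n > 0) cl$mean / ref else NA_real_
  p_acq_p <- prop(acq_p); p_acq_m <- prop(acq_m)
  p_ext_p <- prop(ext_p); p_ext_m <- prop(ext_m)
  tibble(
    id = id,
    scorable = scorable,
    iti_reference = ref,
    n_valid_acq_csp = acq_p$n, n_valid_acq_csm = acq_m$n,
    n_valid_ext_csp = ext_p$n, n_valid_ext_csm = ext_m$n,
    n_valid_acq_iti = acq_iti$n, n_valid_ext_iti = ext_iti$n,
    mean_acq_csp = acq_p$mean, mean_acq_csm = acq_m$mean,
    mean_ext_csp = ext_p$mean, mean_ext_csm = ext_m$mean,
    mean_acq_iti = acq_iti$mean, mean_ext_iti = ext_iti$mean,
    acq_prop_csp = p_acq_p, acq_prop_csm = p_acq_m,
    ext_prop_csp = p_ext_p, ext_prop_csm = p_ext_m,
    acq_differential = if (acq_p$n > 0 && acq_m$n > 0) p_acq_p - p_acq_m else NA_real_,
    ext_differential = if (ext_p$n > 0 && ext_m$n > 0) p_ext_p - p_ext_m else NA_real_
  )
}

#' Retain participants with successful fear acquisition
#'
#' Keeps the rows of a cohort score table whose acquisition differential
#' is strictly positive (CS+ response amplitude exceeding CS-), the
#' subset used for the sensitivity reanalysis of extinction.
#'
#' @param cohort_scores Tibble with an `acq_differential` column (one row
#'   per participant).
#' @return The filtered tibble.
#' @export
filter_successful_acquisition <- function(cohort_scores) {
  dplyr::filter(cohort_scores,
                !is.na(.data$acq_differential) & .data$acq_differential > 0)
}
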
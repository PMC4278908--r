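#' Participant-level parameters of the synthetic EMG generator
#'
#' Describes one simulated participant: background EMG noise level, the
#' peak envelope of an unpotentiated (ITI) startle blink, multiplicative
#' potentiation factors per phase and CS type, blink onset latency and
#' jitter, session-wide startle habituation, non-response and artifact
#' probabilities, trial-to-trial amplitude variability, and clinical
#' covariates.
#'
#' The `potentiation` map expresses the expected blink amplitude to a
#' probed CS as a multiple of the participant's ITI blink amplitude; it is
#' what the ITI-proportional scoring stage should recover.
#'
#' @param group `"MDD"` or `"control"`.
#' @param baseline_noise_rms Background EMG noise RMS in microvolts.
#' @param blink_gain_iti Peak blink envelope (microvolts) of an ITI startle.
#' @param potentiation Named list with entries `acquisition` and
#'   `extinction`, each `c(CSplus = , CSminus = )`; all factors > 0.
#' @param blink_latency_ms Mean blink onset latency after probe onset.
#' @param blink_latency_jitter_ms SD of the per-trial latency.
#' @param habituation_rate Per-probe multiplicative decay of blink gain
#'   across the session, in (0, 1].
#' @param p_nonresponse Probability that a probe elicits no blink.
#' @param p_artifact Per-trial probability of an injected electrode
#'   artifact (step/drift transient).
#' @param amplitude_jitter_sdlog SD (log scale) of per-trial lognormal
#'   amplitude variability (mean 1).
#' @param covariates Named list of clinical covariates (e.g.
#'   `illness_duration_years`, `age`, `bdi`).
#'
#' @return A list of class `participant_params`.
#' @export
participant_params <- function(group = c("control", "MDD"),
                               baseline_noise_rms = 2,
                               blink_gain_iti = 60,
                               potentiation = list(
                                 acquisition = c(CSplus = 1.30, CSminus = 0.85),
                                 extinction = c(CSplus = 1.05, CSminus = 0.70)
                               ),
                               blink_latency_ms = 45,
                               blink_latency_jitter_ms = 5,
                               habituation_rate = 0.985,
                               p_nonresponse = 0.05,
                               p_artifact = 0.02,
                               amplitude_jitter_sdlog = 0.2,
                               covariates = list()) {
  group <- match.arg(group)
  pot <- unlist(potentiation)
  if (any(pot <= 0)) {
    abort("potentiation factors must be positive", class = "startlekit_config_error")
  }
  if (p_nonresponse < 0 || p_nonresponse > 1 || p_artifact < 0 || p_artifact > 1) {
    abort("probabilities must lie in [0, 1]", class = "startlekit_config_error")
  }
  if (habituation_rate <= 0 || habituation_rate > 1) {
    abort("habituation_rate must lie in (0, 1]", class = "startlekit_config_error")
  }
  structure(
    list(group = group, baseline_noise_rms = baseline_noise_rms,
         blink_gain_iti = blink_gain_iti, potentiation = potentiation,
         blink_latency_ms = blink_latency_ms,
         blink_latency_jitter_ms = blink_latency_jitter_ms,
         habituation_rate = habituation_rate, p_nonresponse = p_nonresponse,
         p_artifact = p_artifact,
         amplitude_jitter_sdlog = amplitude_jitter_sdlog,
         covariates = covariates),
    class = "participant_params"
  )
}

# Gamma-shaped blink envelope (shape 3), peak normalised to 1, truncated at
# `width_ms`. The mode sits (shape-1)*scale = 15 ms after burst onset so a
# 45-ms latency puts the processed peak near 65 ms, inside the 40-90 ms
# target window.
blink_envelope <- function(width_ms = 120, fs = 1000, shape = 3, scale_ms = 7.5) {
  t <- seq(0, width_ms - 1000 / fs, by = 1000 / fs)
  env <- t^(shape - 1) * exp(-t / scale_ms)
  env / max(env)
}

# Potentiation factor applying to a probe event row (ITI and habituation
# probes are unpotentiated baseline startles).
potentiation_factor <- function(params, phase, trial_type) {
  if (trial_type %in% c("ITIprobe", "habituation_tone")) return(1)
  unname(params$potentiation[[phase]][[trial_type]])
}

#' Simulate a continuous EMG session
#'
#' Generates a 1 kHz single-channel orbicularis-oculi EMG recording for one
#' participant over a full session schedule. Background activity is
#' stationary band-limited (1-200 Hz) Gaussian noise at the requested RMS,
#' emulating the amplifier's acquisition bandpass. At every probed trial
#' (unless a non-response is drawn) a blink burst is embedded: a 30-300 Hz
#' band-limited carrier under a gamma-shaped envelope of roughly 60 ms
#' effective width starting `blink_latency_ms` (plus jitter) after probe
#' onset, with peak envelope `blink_gain_iti * potentiation[phase, cs] *
#' habituation_rate^(probe ordinal - 1)` times a lognormal trial jitter.
#' The carrier waveform is drawn once per session and reused across blinks,
#' so with jitters disabled the processed blink amplitude is exactly
#' proportional to the programmed peak envelope. Electrode artifacts are
#' step-plus-drift transients injected per trial with probability
#' `p_artifact` at ten times the blink gain.
#'
#' @param schedule A `session_schedule`.
#' @param params A [participant_params()].
#' @param seed Integer seed for all randomness of this session.
#' @param sampling_rate Must be 1000 Hz (resampling is out of scope).
#' @return An [emg_recording()] with a `truth` attribute recording embedded
#'   blink times/amplitudes and artifact windows (generator knowledge for
#'   validation).
#' @export
simulate_emg_session <- function(schedule, params, seed = 1L,
                                 sampling_rate = 1000) {
  if (sampling_rate != 1000) {
    abort("only a 1000 Hz sampling rate is supported",
          class = "startlekit_rate_error")
  }
  fs <- sampling_rate
  n <- as.integer(ceiling((session_duration(schedule) + 2) * fs))
  probes <- probe_events(schedule)
  with_seed(seed, {
    x <- band_noise(n, fs, lo = 1, hi = 200, rms = params$baseline_noise_rms)
    # fixed per-session blink carrier, max-normalised so the envelope peak
    # IS the peak amplitude
    env <- blink_envelope(fs = fs)
    carrier <- bandpass_vector(stats::rnorm(length(env)), fs, 30, 300)
    carrier <- carrier / max(abs(carrier))
    burst_shape <- env * carrier

    blinks <- NULL
    if (nrow(probes) > 0) {
      respond <- stats::runif(nrow(probes)) >= params$p_nonresponse
      lat <- params$blink_latency_ms +
        stats::rnorm(nrow(probes), 0, params$blink_latency_jitter_ms)
      amp_jit <- if (params$amplitude_jitter_sdlog > 0) {
        exp(stats::rnorm(nrow(probes), -params$amplitude_jitter_sdlog^2 / 2,
                         params$amplitude_jitter_sdlog))
      } else {
        rep(1, nrow(probes))
      }
      fac <- purrr::map2_dbl(probes$phase, probes$trial_type,
                             \(p, tt) potentiation_factor(params, p, tt))
      peak <- params$blink_gain_iti * fac *
        params$habituation_rate^(probes$probe_ordinal - 1) * amp_jit
      onset_i <- as.integer(round((probes$probe_onset + lat / 1000) * fs)) + 1L
      for (j in seq_len(nrow(probes))) {
        if (!respond[j]) next
        idx <- onset_i[j] + seq_along(burst_shape) - 1L
        keep <- idx >= 1L & idx <= n
        x[idx[keep]] <- x[idx[keep]] + peak[j] * burst_shape[keep]
      }
      blinks <- tibble(
        probe_onset = probes$probe_onset, phase = probes$phase,
        trial_type = probes$trial_type, responded = respond,
        latency_ms = lat, peak_uv = ifelse(respond, peak, 0)
      )
    }

    # per-trial electrode artifacts: DC step with a drift ramp, 300 ms
    trials <- dplyr::filter(schedule$events,
                            .data$trial_type %in% c("CSplus", "CSminus"))
    art <- NULL
    if (nrow(trials) > 0 && params$p_artifact > 0) {
      hit <- stats::runif(nrow(trials)) < params$p_artifact
      if (any(hit)) {
        t0 <- trials$onset[hit] +
          stats::runif(sum(hit), 0, pmax(trials$duration[hit] - 0.3, 0.1))
        sign <- sample_from(c(-1, 1), sum(hit), replace = TRUE)
        a <- 10 * params$blink_gain_iti
        for (j in seq_along(t0)) {
          i0 <- as.integer(round(t0[j] * fs)) + 1L
          len <- as.integer(0.3 * fs)
          idx <- i0:min(i0 + len - 1L, n)
          ramp <- seq(0, 1, length.out = length(idx))
          x[idx] <- x[idx] + sign[j] * a * (1 + 0.5 * ramp)
        }
        art <- tibble(start_s = t0, end_s = t0 + 0.3)
      }
    }

    rec <- emg_recording(x, sampling_rate = fs, events = schedule,
                         channel_label = "EMG_OO_L")
    attr(rec, "truth") <- list(blinks = blinks, artifacts = art)
    rec
  })
}

#' Cohort design for the synthetic study
#'
#' Population-level description from which [simulate_cohort()] draws
#' participants. Defaults emulate the target study: 37 patients with major
#' depressive disorder (MDD) and 40 healthy controls; differential
#' potentiation during acquisition identical in both groups; a persisting
#' CS+ > CS- differential during extinction in controls but not patients;
#' total illness duration (patients) negatively correlated (target
#' r = -0.40) with the true extinction differential; BDI positively
#' correlated (target r = 0.41) with the true acquisition differential;
#' age correlated 0.42 with illness duration.
#'
#' Cell potentiation means and spreads are sized so that the standardized
#' acquisition CS-effect is about dz = 0.96 and the control extinction
#' differential about dz = 0.74, matching the scale of the reported
#' statistics; see the methods vignette for the derivation.
#'
#' @param n_mdd,n_control Group sizes.
#' @param potentiation_mean Per-group population means of the potentiation
#'   map.
#' @param sd_level Between-participant SD of overall startle reactivity
#'   (shared by both cells of a phase, proportional units).
#' @param sd_diff Between-participant SD of the true CS+ - CS- differential
#'   per phase.
#' @param r_illness_extinction Target correlation between illness duration
#'   and the true extinction differential (patients).
#' @param r_bdi_acquisition Target correlation between BDI and the true
#'   acquisition differential (patients).
#' @param r_age_illness Target correlation between age and illness duration
#'   (patients).
#' @param gain_meanlog,gain_sdlog Lognormal parameters of the ITI blink
#'   gain (microvolts).
#' @param noise_rms_range Uniform range of background noise RMS.
#' @param habituation_range Uniform range of the per-probe habituation
#'   rate.
#' @param p_nonresponse,p_artifact,amplitude_jitter_sdlog,
#'   blink_latency_ms,blink_latency_jitter_ms Passed to every participant.
#' @param p_unaware_mdd,p_unaware_control Probability a participant fails
#'   to identify both CSs (contingency-unaware).
#' @param p_male_mdd,p_male_control Sex distribution.
#' @param seed Master seed; per-participant seeds are derived
#'   deterministically from it.
#'
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_mdd = 37, n_control = 40,
                          potentiation_mean = list(
                            MDD = list(
                              acquisition = c(CSplus = 1.30, CSminus = 0.85),
                              extinction = c(CSplus = 0.80, CSminus = 0.80)
                            ),
                            control = list(
                              acquisition = c(CSplus = 1.30, CSminus = 0.85),
                              extinction = c(CSplus = 1.05, CSminus = 0.70)
                            )
                          ),
                          sd_level = 0.25,
                          sd_diff = 0.47,
                          r_illness_extinction = -0.40,
                          r_bdi_acquisition = 0.41,
                          r_age_illness = 0.42,
                          gain_meanlog = log(60), gain_sdlog = 0.4,
                          noise_rms_range = c(1.5, 3),
                          habituation_range = c(0.975, 0.995),
                          p_nonresponse = 0.05,
                          p_artifact = 0.02,
                          amplitude_jitter_sdlog = 0.2,
                          blink_latency_ms = 45,
                          blink_latency_jitter_ms = 5,
                          p_unaware_mdd = 2 / 37,
                          p_unaware_control = 0,
                          p_male_mdd = 20 / 37,
                          p_male_control = 21 / 40,
                          seed = 1L) {
  if (n_mdd <= 0 || n_control <= 0) {
    abort("group sizes must be positive", class = "startlekit_config_error")
  }
  structure(as.list(environment()), class = "cohort_design")
}

#' Draw the participant-level parameter table of a cohort
#'
#' Samples every participant's true generator parameters and covariates
#' from a [cohort_design()]. This is the common upstream of both the
#' full-EMG cohort simulator and the score-level generator: the true
#' proportional scores (`true_*` columns) are exactly the potentiation
#' factors the downstream pipeline should recover.
#'
#' @param design A [cohort_design()].
#' @return A tibble, one row per participant, with `id`, `group`, `sex`,
#'   covariates, awareness answers, a per-participant `seed`, and list
#'   column `params` of [participant_params()].
#' @export
draw_cohort_params <- function(design) {
  d <- design
  with_seed(d$seed, {
    rows <- purrr::map(seq_len(d$n_mdd + d$n_control), function(i) {
      group <- if (i <= d$n_mdd) "MDD" else "control"
      pm <- d$potentiation_mean[[group]]
      # shared standardized deviates so covariates can be linked to the
      # participant's true differentials
      z_acq_diff <- stats::rnorm(1)
      z_ext_diff <- stats::rnorm(1)
      l_acq <- stats::rnorm(1, 0, d$sd_level)
      l_ext <- stats::rnorm(1, 0, d$sd_level)
      cell <- function(mu, l, zd, s) max(mu + l + s * zd / 2, 0.05)
      pot <- list(
        acquisition = c(
          CSplus = cell(pm$acquisition[["CSplus"]], l_acq, z_acq_diff, d$sd_diff),
          CSminus = cell(pm$acquisition[["CSminus"]], l_acq, -z_acq_diff, d$sd_diff)
        ),
        extinction = c(
          CSplus = cell(pm$extinction[["CSplus"]], l_ext, z_ext_diff, d$sd_diff),
          CSminus = cell(pm$extinction[["CSminus"]], l_ext, -z_ext_diff, d$sd_diff)
        )
      )
      mix <- function(r, z_target, z_free) r * z_target + sqrt(1 - r^2) * z_free
      if (group == "MDD") {
        z_ill <- mix(d$r_illness_extinction, z_ext_diff, stats::rnorm(1))
        illness <- max(10.6 + 9.5 * z_ill, 0.3)
        bdi <- max(29.2 + 10.5 * mix(d$r_bdi_acquisition, z_acq_diff, stats::rnorm(1)), 0)
        age <- max(38.4 + 12.4 * mix(d$r_age_illness, z_ill, stats::rnorm(1)), 18)
        unaware <- stats::runif(1) < d$p_unaware_mdd
        male <- stats::runif(1) < d$p_male_mdd
      } else {
        illness <- 0
        bdi <- max(1.9 + 2.9 * stats::rnorm(1), 0)
        age <- max(37.3 + 10.5 * stats::rnorm(1), 18)
        unaware <- stats::runif(1) < d$p_unaware_control
        male <- stats::runif(1) < d$p_male_control
      }
      params <- participant_params(
        group = group,
        baseline_noise_rms = stats::runif(1, d$noise_rms_range[1], d$noise_rms_range[2]),
        blink_gain_iti = exp(stats::rnorm(1, d$gain_meanlog, d$gain_sdlog)),
        potentiation = pot,
        blink_latency_ms = d$blink_latency_ms,
        blink_latency_jitter_ms = d$blink_latency_jitter_ms,
        habituation_rate = stats::runif(1, d$habituation_range[1], d$habituation_range[2]),
        p_nonresponse = d$p_nonresponse,
        p_artifact = d$p_artifact,
        amplitude_jitter_sdlog = d$amplitude_jitter_sdlog,
        covariates = list(illness_duration_years = illness, age = age, bdi = bdi)
      )
      tibble(
        id = sprintf("S%03d", i),
        group = group,
        sex = if (male) "m" else "f",
        age = age,
        illness_duration_years = illness,
        bdi = bdi,
        cs_plus_correct = !unaware,
        cs_minus_correct = !unaware,
        true_acq_csp = pot$acquisition[["CSplus"]],
        true_acq_csm = pot$acquisition[["CSminus"]],
        true_ext_csp = pot$extinction[["CSplus"]],
        true_ext_csm = pot$extinction[["CSminus"]],
        seed = derive_seed(d$seed, i),
        params = list(params)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate a full synthetic cohort of EMG sessions
#'
#' Draws the participant table with [draw_cohort_params()], builds one
#' pseudorandomized schedule per participant (schedule seed derived from
#' the participant seed) and simulates each EMG session. Group sizes are
#' exact and the whole cohort is a deterministic function of the design
#' seed.
#'
#' @param design A [cohort_design()].
#' @param schedule_cfg A [schedule_config()]; its seed field is replaced
#'   per participant.
#' @return A list with `participants` (the parameter/covariate tibble) and
#'   `sessions`, a list of `list(schedule, recording)` per participant.
#'   For large cohorts prefer streaming via [run_pipeline()], which never
#'   holds more than one recording in memory.
#' @export
simulate_cohort <- function(design, schedule_cfg = schedule_config()) {
  pt <- draw_cohort_params(design)
  sessions <- purrr::map(seq_len(nrow(pt)), function(i) {
    cfg <- schedule_cfg
    cfg$seed <- derive_seed(pt$seed[i], 1L)
    sched <- build_schedule(cfg)
    rec <- simulate_emg_session(sched, pt$params[[i]], seed = pt$seed[i])
    list(schedule = sched, recording = rec)
  })
  list(participants = pt, sessions = sessions)
}

#' Score-level cohort generator
#'
#' Draws per-participant proportional scores directly from the design's
#' participant-level truth, adding Gaussian trial-sampling noise of the
#' size implied by averaging `n_cs_probes` lognormal trials against an
#' `n_iti_probes`-trial ITI reference. This is the fast path for
#' Monte-Carlo calibration of the statistics layer (e.g. type-I error of
#' the interaction test), where simulating full EMG per replicate would
#' be prohibitive; the EMG path is validated separately.
#'
#' @param design A [cohort_design()].
#' @param n_cs_probes,n_iti_probes Probe counts per cell that set the
#'   measurement-noise scale.
#' @return A tibble with one row per participant: proportional scores per
#'   phase and CS type plus differentials, as produced by the scoring
#'   stage.
#' @export
simulate_cohort_scores <- function(design, n_cs_probes = 6, n_iti_probes = 4) {
  pt <- draw_cohort_params(design)
  s <- design$amplitude_jitter_sdlog
  se_cell <- sqrt(s^2 / n_cs_probes + s^2 / n_iti_probes)
  with_seed(derive_seed(design$seed, 999983L), {
    n <- nrow(pt)
    noisy <- function(mu) mu * (1 + stats::rnorm(n, 0, se_cell))
    pt |>
      dplyr::mutate(
        acq_prop_csp = noisy(.data$true_acq_csp),
        acq_prop_csm = noisy(.data$true_acq_csm),
        ext_prop_csp = noisy(.data$true_ext_csp),
        ext_prop_csm = noisy(.data$true_ext_csm),
        acq_differential = .data$acq_prop_csp - .data$acq_prop_csm,
        ext_differential = .data$ext_prop_csp - .data$ext_prop_csm
      ) |>
      dplyr::select(-"params")
  })
}
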
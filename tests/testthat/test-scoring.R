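fs <- 1000

# quiet baseline + hand-built response bump with known onset/peak
bump_signal <- function(onset_ms, peak = 80, probe_i = 1000, n = 2000,
                        width_ms = 40, noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  x <- abs(rnorm(n, 0.5, noise_sd))
  i0 <- probe_i + onset_ms
  ramp <- peak * sin(seq(0, pi, length.out = width_ms))^2
  x[i0:(i0 + width_ms - 1)] <- x[i0:(i0 + width_ms - 1)] + ramp
  as_processed(x)
}

test_that("flat signals and degenerate baselines yield no_crossing", {
  d <- detect_startle_response(as_processed(numeric(2000)), probe_onset_s = 1)
  expect_false(d$valid)
  expect_equal(d$invalid_reason, "no_crossing")
  expect_equal(d$baseline_sd, 0)
})

test_that("an embedded burst is detected with its known onset and amplitude", {
  sig <- bump_signal(onset_ms = 55, peak = 80)
  d <- detect_startle_response(sig, probe_onset_s = 1)
  expect_true(d$valid)
  # threshold crossing happens within a couple of samples of the true onset
  expect_gte(d$onset_latency_ms, 55)
  expect_lte(d$onset_latency_ms, 60)
  # amplitude is the baseline-subtracted peak in the 40-90 ms window
  expect_equal(d$amplitude, 80, tolerance = 0.02)
})

test_that("the same burst shifted past the latency window is late_onset", {
  sig <- bump_signal(onset_ms = 150, peak = 80)
  d <- detect_startle_response(sig, probe_onset_s = 1)
  expect_false(d$valid)
  expect_equal(d$invalid_reason, "late_onset")
})

test_that("a response that never returns below threshold is rejected", {
  set.seed(2)
  x <- abs(rnorm(2000, 0.5, 0.2))
  x[1030:1400] <- x[1030:1400] + 50 # sustained elevation past 110 ms
  d <- detect_startle_response(as_processed(x), probe_onset_s = 1)
  expect_false(d$valid)
  expect_equal(d$invalid_reason, "no_return")
})

test_that("probes without room for a full baseline error out", {
  expect_error(detect_startle_response(as_processed(numeric(600)),
                                       probe_onset_s = 0.3),
               class = "startlekit_window_error")
})

test_that("artifact-masked windows invalidate the trial", {
  sig <- bump_signal(onset_ms = 55)
  sig$artifact_mask[1060:1080] <- TRUE
  d <- detect_startle_response(sig, probe_onset_s = 1)
  expect_false(d$valid)
  expect_equal(d$invalid_reason, "artifact")
})

test_that("detection agrees with a brute-force per-sample oracle", {
  set.seed(99)
  for (k in 1:100) {
    n <- 2000
    x <- abs(rnorm(n, 0.4, runif(1, 0.05, 0.5)))
    if (runif(1) < 0.7) {
      onset <- sample(10:160, 1)
      w <- sample(c(20, 40, 80), 1)
      amp <- runif(1, 0.5, 30)
      i0 <- 1000 + onset
      x[i0:(i0 + w - 1)] <- x[i0:(i0 + w - 1)] +
        amp * sin(seq(0, pi, length.out = w))^2
    }
    got <- detect_startle_response(as_processed(x), probe_onset_s = 1)
    want <- brute_force_detect(x, fs, probe_s = 1)
    expect_equal(got$valid, want$valid)
    if (want$valid) {
      expect_equal(got$onset_latency_ms, want$onset)
      expect_equal(got$amplitude, want$amplitude)
    }
  }
})

test_that("false-valid rate on pure noise decreases with threshold_k", {
  set.seed(7)
  trials <- purrr::map(1:150, \(k) abs(rnorm(2000, 0.4, 0.3)))
  rate <- vapply(c(2, 3, 4), function(k) {
    cfg <- response_window_config(threshold_k = k)
    mean(vapply(trials,
                \(x) detect_startle_response(as_processed(x), 1, cfg)$valid,
                logical(1)))
  }, numeric(1))
  expect_true(all(diff(rate) <= 0))
  expect_lt(rate[2], 0.35)
})

make_responses <- function(phase, type, amps, valid = TRUE) {
  tibble::tibble(
    phase = phase, trial_type = type,
    probe_ordinal = seq_along(amps), probe_onset_s = seq_along(amps),
    valid = rep_len(valid, length(amps)),
    invalid_reason = ifelse(rep_len(valid, length(amps)), "none", "no_crossing"),
    onset_latency_ms = 50, amplitude = amps,
    baseline_mean = 0, baseline_sd = 0.1
  )
}

test_that("proportional scores follow their definition on hand-built data", {
  resp <- dplyr::bind_rows(
    make_responses("habituation", "habituation_tone", rep(100, 3)),
    make_responses("acquisition", "CSplus", c(2, 4, 6, 8, 10, 12)),
    make_responses("acquisition", "CSminus", rep(8, 6)),
    make_responses("acquisition", "ITIprobe", rep(8, 4)),
    make_responses("extinction", "CSplus", rep(8, 6)),
    make_responses("extinction", "CSminus", rep(8, 6)),
    make_responses("extinction", "ITIprobe", rep(6, 4))
  )
  sc <- score_participant(resp)
  expect_true(sc$scorable)
  expect_equal(sc$iti_reference, 8)
  expect_equal(sc$acq_prop_csp, 0.875) # mean 7 over reference 8
  expect_equal(sc$acq_prop_csm, 1.0)
  expect_equal(sc$ext_prop_csp, 1.0)
  expect_equal(sc$acq_differential, -0.125)
  expect_equal(sc$ext_differential, 0)
  # huge habituation amplitudes contributed to no cell
  expect_equal(sc$n_valid_acq_csp, 6)
  expect_false(any(unlist(sc[1, grepl("^mean_", names(sc))]) == 100))
  # extinction is referenced to the acquisition ITI mean, not its own
  expect_equal(sc$mean_ext_iti, 6)
  expect_equal(sc$ext_prop_csm, 1.0)
})

test_that("invalid trials are excluded and unscorable participants flagged", {
  resp <- dplyr::bind_rows(
    make_responses("acquisition", "CSplus", c(10, 10, 999), valid = c(TRUE, TRUE, FALSE)),
    make_responses("acquisition", "CSminus", c(5, 5)),
    make_responses("acquisition", "ITIprobe", rep(10, 2)),
    make_responses("extinction", "CSplus", 8),
    make_responses("extinction", "CSminus", 8)
  )
  sc <- score_participant(resp)
  expect_equal(sc$n_valid_acq_csp, 2)
  expect_equal(sc$acq_prop_csp, 1.0) # the invalid 999 never enters
  no_iti <- dplyr::filter(resp, trial_type != "ITIprobe")
  sc2 <- score_participant(no_iti)
  expect_false(sc2$scorable)
  expect_true(is.na(sc2$acq_prop_csp))
  expect_true(is.na(sc2$ext_differential))
})

test_that("successful-acquisition filtering is strict and matches a recount", {
  set.seed(13)
  cohort <- tibble::tibble(
    id = sprintf("S%02d", 1:40),
    acq_differential = c(round(rnorm(38, 0.2, 0.5), 3), 0, NA)
  )
  kept <- filter_successful_acquisition(cohort)
  expect_equal(nrow(kept), sum(cohort$acq_differential > 0, na.rm = TRUE))
  expect_false(any(kept$acq_differential <= 0))
  expect_false(any(is.na(kept$acq_differential)))
})
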
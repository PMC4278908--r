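test_that("a silent non-responder produces an identically zero recording", {
  s <- build_schedule(mini_schedule_config())
  p <- participant_params(baseline_noise_rms = 0, p_nonresponse = 1,
                          p_artifact = 0)
  rec <- simulate_emg_session(s, p, seed = 1)
  expect_true(all(rec$samples == 0))
})

test_that("embedded burst count is bounded by (and can equal) the probe count", {
  s <- build_schedule(mini_schedule_config())
  n_probes <- nrow(probe_events(s))
  p1 <- participant_params(p_nonresponse = 0.5, p_artifact = 0)
  r1 <- simulate_emg_session(s, p1, seed = 5)
  expect_lte(sum(attr(r1, "truth")$blinks$responded), n_probes)
  p2 <- participant_params(p_nonresponse = 0, p_artifact = 0)
  r2 <- simulate_emg_session(s, p2, seed = 5)
  expect_equal(sum(attr(r2, "truth")$blinks$responded), n_probes)
})

test_that("sessions are deterministic and reject unsupported rates", {
  s <- build_schedule(mini_schedule_config())
  p <- participant_params()
  a <- simulate_emg_session(s, p, seed = 42)
  b <- simulate_emg_session(s, p, seed = 42)
  expect_identical(a$samples, b$samples)
  expect_error(simulate_emg_session(s, p, seed = 1, sampling_rate = 2000),
               class = "startlekit_rate_error")
})

test_that("recordings scale linearly in gain and scores are gain-invariant", {
  s <- build_schedule(mini_schedule_config())
  p1 <- participant_params(blink_gain_iti = 60, baseline_noise_rms = 2,
                           p_artifact = 0)
  p2 <- p1
  p2$blink_gain_iti <- 60 * 3
  p2$baseline_noise_rms <- 2 * 3
  r1 <- simulate_emg_session(s, p1, seed = 9)
  r2 <- simulate_emg_session(s, p2, seed = 9)
  expect_equal(r2$samples, 3 * r1$samples, tolerance = 1e-10)

  score <- function(r) {
    score_participant(detect_responses(preprocess_emg(r), schedule = s))
  }
  s1 <- score(r1)
  s2 <- score(r2)
  expect_equal(s1$acq_prop_csp, s2$acq_prop_csp, tolerance = 1e-8)
  expect_equal(s1$ext_differential, s2$ext_differential, tolerance = 1e-8)
  expect_equal(s2$iti_reference, 3 * s1$iti_reference, tolerance = 1e-8)
})

test_that("noise-free processed peaks match an independent oracle chain", {
  cfg <- schedule_config(n_habituation_tones = 0, n_cs_plus = 1, n_cs_minus = 1,
                         reinforcement_fraction = 0, probe_fraction_cs = 1,
                         n_iti_probes = 1, iti_durations_s = 10,
                         habituation_itis_s = 10, lead_in_s = 3,
                         phase_gap_s = 3, seed = 2)
  s <- build_schedule(cfg)
  rec <- simulate_emg_session(s, clean_params(), seed = 4)
  got <- preprocess_emg(rec)$samples
  want <- oracle_preprocess(rec$samples)
  probes <- probe_events(s)
  for (t in probes$probe_onset) {
    w <- (round(t * 1000) + 40):(round(t * 1000) + 90)
    expect_equal(max(got[w]), max(want[w]), tolerance = 0.01)
    expect_gt(max(got[w]), 0)
  }
})

test_that("noise-free scoring recovers the potentiation factors exactly", {
  s <- build_schedule(schedule_config(seed = 6))
  p <- clean_params()
  rec <- simulate_emg_session(s, p, seed = 6)
  sc <- score_participant(detect_responses(preprocess_emg(rec), schedule = s))
  expect_true(sc$scorable)
  expect_equal(sc$acq_prop_csp, p$potentiation$acquisition[["CSplus"]],
               tolerance = 0.01)
  expect_equal(sc$acq_prop_csm, p$potentiation$acquisition[["CSminus"]],
               tolerance = 0.01)
  expect_equal(sc$ext_prop_csp, p$potentiation$extinction[["CSplus"]],
               tolerance = 0.01)
  expect_equal(sc$ext_prop_csm, p$potentiation$extinction[["CSminus"]],
               tolerance = 0.01)
})

test_that("noisy scoring recovers the potentiation factors without bias", {
  s <- build_schedule(schedule_config(seed = 12))
  p <- participant_params(p_nonresponse = 0, p_artifact = 0,
                          habituation_rate = 1)
  reps <- 40
  sc <- purrr::map_dfr(seq_len(reps), function(k) {
    rec <- simulate_emg_session(s, p, seed = 3000 + k)
    score_participant(detect_responses(preprocess_emg(rec), schedule = s))
  })
  for (cell in c("acq_prop_csp", "acq_prop_csm", "ext_prop_csp", "ext_prop_csm")) {
    truth <- switch(cell,
                    acq_prop_csp = p$potentiation$acquisition[["CSplus"]],
                    acq_prop_csm = p$potentiation$acquisition[["CSminus"]],
                    ext_prop_csp = p$potentiation$extinction[["CSplus"]],
                    ext_prop_csm = p$potentiation$extinction[["CSminus"]])
    se <- sd(sc[[cell]]) / sqrt(reps)
    expect_lt(abs(mean(sc[[cell]]) - truth), 3.5 * se + 0.02 * truth)
  }
})

test_that("cohorts have exact sizes, determinism, and linked covariates", {
  d <- cohort_design(n_mdd = 37, n_control = 40, seed = 31)
  pt <- draw_cohort_params(d)
  expect_equal(nrow(pt), 77)
  expect_equal(sum(pt$group == "MDD"), 37)
  expect_identical(pt$seed, draw_cohort_params(d)$seed)
  expect_identical(pt$true_ext_csp, draw_cohort_params(d)$true_ext_csp)
  expect_error(cohort_design(n_mdd = 0), class = "startlekit_config_error")

  # the illness-duration link targets r = -0.40 to the true extinction
  # differential: check on a large sample within sampling error
  big <- draw_cohort_params(cohort_design(n_mdd = 2000, n_control = 2,
                                          seed = 77))
  mdd <- big[big$group == "MDD", ]
  r <- cor(mdd$illness_duration_years, mdd$true_ext_csp - mdd$true_ext_csm)
  expect_lt(abs(r - (-0.40)), 0.07)
})

test_that("small full-EMG cohorts are reproducible end to end", {
  d <- cohort_design(n_mdd = 2, n_control = 2, seed = 8)
  cfg <- mini_schedule_config()
  a <- simulate_cohort(d, cfg)
  b <- simulate_cohort(d, cfg)
  expect_equal(length(a$sessions), 4)
  expect_identical(a$sessions[[1]]$recording$samples,
                   b$sessions[[1]]$recording$samples)
  expect_identical(a$sessions[[3]]$schedule$events,
                   b$sessions[[3]]$schedule$events)
})

test_that("a group-specific extinction differential is recovered with the right sign", {
  # controls keep CS+ > CS- in extinction, patients do not: the interaction
  # contrast (control differential minus patient differential) must come out
  # positive in nearly all replicate cohorts at study scale
  hits <- purrr::map_lgl(1:100, function(k) {
    sc <- simulate_cohort_scores(cohort_design(seed = 5000 + k))
    d_ctl <- mean(sc$ext_differential[sc$group == "control"])
    d_mdd <- mean(sc$ext_differential[sc$group == "MDD"])
    d_ctl > d_mdd
  })
  expect_gte(mean(hits), 0.9)
})
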
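# Shared fixtures (built in code) and independent brute-force oracles.

# Small, fast paradigm for unit tests (full-size defaults are exercised in
# the acceptance suite).
mini_schedule_config <- function(seed = 1L, ...) {
  schedule_config(
    n_habituation_tones = 3, n_cs_plus = 4, n_cs_minus = 4,
    reinforcement_fraction = 0.5, probe_fraction_cs = 0.5,
    n_iti_probes = 2, iti_durations_s = c(6, 8),
    habituation_itis_s = c(6, 8), lead_in_s = 5, phase_gap_s = 5,
    seed = seed, ...
  )
}

# Deterministic, noise-free participant: proportional scores must equal the
# potentiation factors exactly.
clean_params <- function(...) {
  participant_params(
    baseline_noise_rms = 0, p_nonresponse = 0, p_artifact = 0,
    amplitude_jitter_sdlog = 0, blink_latency_jitter_ms = 0,
    habituation_rate = 1, ...
  )
}

# Wrap a bare vector as a processed signal for detector tests.
as_processed <- function(x, fs = 1000) {
  structure(
    list(samples = x, sampling_rate = fs, events = NULL, raw_samples = x,
         artifact_mask = logical(length(x)), processing_log = "direct"),
    class = "processed_signal"
  )
}

# Brute-force startle detector: explicit per-sample scan of the response
# definition, kept deliberately naive and independent of the package path.
brute_force_detect <- function(x, fs, probe_s, baseline_ms = 500,
                               k = 3, val_win = c(20, 110), amp_win = c(40, 90)) {
  p <- round(probe_s * fs) + 1
  base <- x[(p - baseline_ms * fs / 1000):(p - 1)]
  bm <- mean(base)
  bs <- sd(base)
  thr <- bm + k * bs
  onset <- NA_real_
  crossed <- FALSE
  returned <- FALSE
  for (i in (p + val_win[1] * fs / 1000):(p + val_win[2] * fs / 1000)) {
    if (!crossed && x[i] > thr) {
      crossed <- TRUE
      onset <- (i - p) * 1000 / fs
    } else if (crossed && x[i] <= thr) {
      returned <- TRUE
      break
    }
  }
  valid <- crossed && (returned || bs == 0)
  amp <- NA_real_
  if (valid) {
    w <- x[(p + amp_win[1] * fs / 1000):(p + amp_win[2] * fs / 1000)]
    amp <- max(max(w) - bm, 0)
  }
  list(valid = valid, onset = if (valid) onset else NA_real_, amplitude = amp)
}

# Independent 2x2 mixed-ANOVA oracle: every F built from t statistics on
# subject means / differences (unweighted Type-III contrasts), no shared
# code with the package's SS route.
oracle_mixed_anova <- function(group, csp, csm) {
  g <- sort(unique(group))
  d <- csp - csm
  m <- (csp + csm) / 2
  n1 <- sum(group == g[1]); n2 <- sum(group == g[2])
  sp2_m <- (sum((m[group == g[1]] - mean(m[group == g[1]]))^2) +
              sum((m[group == g[2]] - mean(m[group == g[2]]))^2)) / (n1 + n2 - 2)
  t_grp <- (mean(m[group == g[1]]) - mean(m[group == g[2]])) /
    sqrt(sp2_m * (1 / n1 + 1 / n2))
  sp2_d <- (sum((d[group == g[1]] - mean(d[group == g[1]]))^2) +
              sum((d[group == g[2]] - mean(d[group == g[2]]))^2)) / (n1 + n2 - 2)
  t_cs <- ((mean(d[group == g[1]]) + mean(d[group == g[2]])) / 2) /
    sqrt(sp2_d * (1 / (4 * n1) + 1 / (4 * n2)))
  t_int <- (mean(d[group == g[1]]) - mean(d[group == g[2]])) /
    sqrt(sp2_d * (1 / n1 + 1 / n2))
  c(group = t_grp^2, cs_type = t_cs^2, interaction = t_int^2)
}

# Direct-formula statistical oracles.
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}
oracle_pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}
oracle_r <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Independent preprocessing chain for generator-knowledge checks: direct
# full-length DFT gain application (no reflection padding) + convolution
# moving average. Agrees with the package chain away from the edges.
oracle_preprocess <- function(x, fs = 1000) {
  gain <- function(f, fc) {
    r <- (f / fc)^8
    r / (1 + r)
  }
  apply_gain <- function(x, fc) {
    m <- length(x)
    f <- pmin(0:(m - 1), m - (0:(m - 1))) * fs / m
    Re(fft(fft(x) * gain(f, fc), inverse = TRUE)) / m
  }
  y <- abs(apply_gain(x, 65))
  y <- as.numeric(stats::filter(y, rep(1 / 40, 40), sides = 2))
  y[is.na(y)] <- 0
  pmax(apply_gain(y, 2), 0)
}
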
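# Internal DSP primitives.
#
# No IIR filtering package is available, so the two high-pass stages are
# realised as zero-phase frequency-domain filters whose gain is the SQUARED
# magnitude response of an analog 4th-order Butterworth high-pass: this is
# the steady-state equivalent of filtering forward and backward with that
# Butterworth (filtfilt), without its edge-transient and low-cutoff
# numerical-stability issues. Edges are handled by reflection padding.

# Squared-magnitude (forward-backward) gain of an order-n Butterworth
# high-pass at frequency f (Hz) for cutoff fc: |H(f)|^2.
butter_hp_gain2 <- function(f, fc, order = 4) {
  r <- (f / fc)^(2 * order)
  r / (1 + r)
}

# Low-pass counterpart, used only by the synthetic band-limited generators.
butter_lp_gain2 <- function(f, fc, order = 4) {
  1 / (1 + (f / fc)^(2 * order))
}

# Apply a real, even, frequency-dependent gain to x by FFT with reflection
# padding. `gain_fun(f)` receives non-negative frequencies in Hz.
fft_apply_gain <- function(x, fs, gain_fun, pad = NULL) {
  n <- length(x)
  if (n < 8) {
    return(x - mean(x) * gain_fun(0) * 0) # degenerate; handled by callers
  }
  pad <- pad %||% min(n - 1L, 1000L)
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  m <- stats::nextn(length(xp), c(2L, 3L, 5L))
  xp <- c(xp, numeric(m - length(xp)))
  k <- 0:(m - 1)
  f <- pmin(k, m - k) * (fs / m)
  g <- gain_fun(f)
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / m
  y[pad + seq_len(n)]
}

# Zero-phase high-pass with squared 4th-order Butterworth magnitude.
zero_phase_highpass <- function(x, fs, fc, order = 4) {
  pad <- min(length(x) - 1L, max(200L, as.integer(round(2 * fs / fc))))
  fft_apply_gain(x, fs, function(f) butter_hp_gain2(f, fc, order), pad = pad)
}

# Centered moving average over `width` samples (even widths span
# i - width/2 .. i + width/2 - 1), edges by reflection.
moving_average <- function(x, width) {
  n <- length(x)
  w <- as.integer(width)
  if (w <= 1L || n == 0L) return(x)
  half_l <- w %/% 2L
  half_r <- w - half_l - 1L
  pad_l <- rev(x[seq_len(min(half_l, n - 1L)) + 1L])
  if (length(pad_l) < half_l) pad_l <- c(rep(x[1L], half_l - length(pad_l)), pad_l)
  pad_r <- rev(x[n - seq_len(min(half_r, n - 1L))])
  if (length(pad_r) < half_r) pad_r <- c(pad_r, rep(x[n], half_r - length(pad_r)))
  xp <- c(pad_l, x, pad_r)
  cs <- c(0, cumsum(xp))
  (cs[(w + 1L):(length(xp) + 1L)] - cs[1L:(length(xp) - w + 1L)]) / w
}

# Stationary Gaussian band-limited noise of exact RMS, synthesised in the
# frequency domain (single inverse FFT). Band edges are soft (4th-order
# Butterworth magnitudes), emulating an analog acquisition bandpass.
band_noise <- function(n, fs, lo, hi, rms) {
  if (n == 0L || rms <= 0) return(numeric(n))
  m <- stats::nextn(n, c(2L, 3L, 5L))
  k <- 0:(m - 1)
  f <- pmin(k, m - k) * (fs / m)
  g <- sqrt(butter_hp_gain2(f, lo, 4) * butter_lp_gain2(f, hi, 4))
  # white Gaussian sequence shaped in frequency: FFT of white noise has the
  # right Hermitian structure automatically
  w <- stats::rnorm(m)
  y <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  s <- sqrt(mean(y^2))
  if (s == 0) return(numeric(n))
  y * (rms / s)
}

# Band-pass an existing short vector (blink carrier shaping).
bandpass_vector <- function(x, fs, lo, hi) {
  fft_apply_gain(x, fs,
                 function(f) sqrt(butter_hp_gain2(f, lo, 4) * butter_lp_gain2(f, hi, 4)),
                 pad = min(length(x) - 1L, 200L))
}
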
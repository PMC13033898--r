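# Shared builders for small, fully deterministic fixtures. Everything is
# generated in code at test time; nothing is read from disk.

# A gamma_series assembled by hand (no simulator) for DSP-level tests.
make_gamma_series <- function(values, timing, tof_axis) {
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  structure(
    list(values = values, tof_axis = tof_axis, timing = timing,
         amplitude = rep(1, length(tof_axis)), noise = noise_model(),
         seed = 0, truth = NULL),
    class = "gamma_series"
  )
}

# Default test timing: desk-scale (50 kHz sweep, 512 samples/sweep).
test_timing <- function() desk_timing()

# Homogeneous tissue-like medium calibrated to 28 kHz at 1 ns.
test_medium <- function() {
  calibrate_medium(homogeneous_medium(), 28e3, 1e-9)
}

# IRF on a fine grid for simulator runs.
test_irf <- function(fwhm = 120e-12) {
  synth_irf(fwhm, seq(0, 1.5e-9, by = 12e-12))
}

# Brute-force O(N^2) inverse DFT retaining nonnegative-delay bins: the
# independent oracle for ifft_gamma.
brute_ifft <- function(y) {
  m <- length(y)
  k <- floor(m / 2) + 1L
  vapply(0:(k - 1), function(b) {
    sum(y * exp(2i * pi * (0:(m - 1)) * b / m)) / m
  }, complex(1))
}

# Direct lag-product autocorrelation estimator (full stream, unbiased):
# oracle for the simulator's decorrelation law.
lag_autocorr <- function(x, lags) {
  n <- length(x)
  vapply(lags, function(j) {
    mean(Conj(x[seq_len(n - j)]) * x[seq.int(1 + j, n)])
  }, complex(1))
}

# Textbook OLS slope and slope SE: oracle for sliding_gradient.
ols_slope_se <- function(x, y) {
  xc <- x - mean(x)
  b <- sum(xc * y) / sum(xc^2)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  list(slope = b, se = sqrt(rss / (length(x) - 2) / sum(xc^2)))
}

# Row-wise z-scoring (as segment_pulses applies after resampling).
zscore_rows <- function(m) {
  t(apply(m, 1, function(r) (r - mean(r)) / sd(r)))
}

# A periodic pulsatile trace sampled at `rate` whose beats are identical.
periodic_pulse_trace <- function(rate = 50, n_beats = 15, beat_s = 1) {
  per <- round(beat_s * rate)
  beat <- tofflow:::.cardiac_waveform(seq(0, 1 - 1 / per, length.out = per))
  rep(beat, n_beats)
}
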
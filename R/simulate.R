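#' Cardiac pulsatility model for the decay rate
#'
#' Scales the ToF-resolved decay rate between a diastolic and a systolic value
#' along a periodic cardiac waveform (fast systolic upstroke, exponential
#' diastolic decay) that is shared across channels. The default diastolic and
#' systolic scale factors of 15/28 and 50/28 reproduce, when applied to a
#' medium calibrated to a 28 kHz mean at 1 ns, the in vivo median diastolic to
#' systolic decay-rate range of 15 to 50 kHz at that ToF.
#'
#' @param heart_rate beats per second (Hz).
#' @param diastolic_scale,systolic_scale multiplicative factors applied to the
#'   medium's decay-rate profile at end-diastole / peak systole
#'   (`diastolic_scale <= systolic_scale`).
#' @param beat_jitter standard deviation of beat-to-beat period jitter, s.
#' @return An object of class `pulsatility_model`.
#' @export
pulsatility_model <- function(heart_rate = 1.0, diastolic_scale = 15 / 28,
                              systolic_scale = 50 / 28, beat_jitter = 0) {
  stopifnot(heart_rate > 0, diastolic_scale > 0,
            diastolic_scale <= systolic_scale, beat_jitter >= 0,
            beat_jitter < 0.5 / heart_rate)
  structure(
    list(heart_rate = heart_rate, diastolic_scale = diastolic_scale,
         systolic_scale = systolic_scale, beat_jitter = beat_jitter),
    class = "pulsatility_model"
  )
}

# Normalized cardiac waveform on phase in [0, 1): 0 at end-diastole, 1 at the
# systolic peak. Sinusoidal upstroke over the first 15% of the beat, then an
# exponential diastolic decay with time constant 25% of the beat.
.cardiac_waveform <- function(phase) {
  rise <- 0.15
  tau <- 0.25
  w <- numeric(length(phase))
  up <- phase < rise
  w[up] <- sin(pi / 2 * phase[up] / rise)
  w[!up] <- exp(-(phase[!up] - rise) / tau)
  w
}

# Beat phase for each time point, with optional per-beat period jitter
# (consumes the active RNG stream). Returns phase in [0, 1) plus beat onsets.
.beat_phase <- function(times, pm) {
  t_end <- max(times)
  n_beats <- ceiling(t_end * pm$heart_rate) + 2L
  periods <- rep(1 / pm$heart_rate, n_beats)
  if (pm$beat_jitter > 0) {
    periods <- pmax(periods + rnorm(n_beats, 0, pm$beat_jitter),
                    0.3 / pm$heart_rate)
  }
  onsets <- c(0, cumsum(periods))
  idx <- findInterval(times, onsets)
  phase <- (times - onsets[idx]) / periods[pmin(idx, n_beats)]
  list(phase = pmin(phase, 1 - 1e-12), onsets = onsets[onsets <= t_end])
}

#' Additive noise model for simulated streams
#'
#' @param gamma_noise_sd standard deviation of circular complex Gaussian noise
#'   added per Gamma sample (same units as the field amplitude, which is
#'   normalized to 1 at the TPSF peak bin).
#' @param adc_noise_sd standard deviation of real Gaussian noise added to each
#'   digitized interferogram sample.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gamma_noise_sd = 0, adc_noise_sd = 0) {
  stopifnot(gamma_noise_sd >= 0, adc_noise_sd >= 0)
  structure(list(gamma_noise_sd = gamma_noise_sd,
                 adc_noise_sd = adc_noise_sd),
            class = "noise_model")
}

# Deterministic child seed per (channel, gate) stream, below 2^31.
.child_seed <- function(seed, channel, gate) {
  (as.double(seed) * 48271 + channel * 100003 + gate * 7919) %% 2147483629
}

#' Simulate mutual-coherence (Gamma) streams with known ground truth
#'
#' Generates, per ToF gate and detection channel, a complex field stream at
#' the sweep rate whose autocorrelation decays exactly as `exp(-xi(ToF) tau)`:
#' a first-order autoregressive complex Ornstein-Uhlenbeck process
#' `Gamma[n+1] = rho[n] Gamma[n] + sqrt(1 - rho[n]^2) eps[n]` with
#' `rho[n] = exp(-xi(ToF, t[n]) dt)` and circular complex Gaussian
#' innovations. The per-gate amplitude follows the square root of the
#' IRF-convolved TPSF (so mean `|Gamma|^2` traces the TPSF), physiology is
#' shared across channels, and speckle and additive noise are independent per
#' channel. Ground-truth decay rates are returned alongside.
#'
#' @param medium a [medium_spec()].
#' @param timing a [sweep_timing()].
#' @param tof_gates ToF gate centers, s.
#' @param duration recording length, s.
#' @param n_channels number of detection channels.
#' @param irf optional `irf_record` used to shape the amplitude profile; when
#'   `NULL` the raw TPSF is used.
#' @param pulsatility optional [pulsatility_model()]; `NULL` for static
#'   dynamics.
#' @param noise a [noise_model()].
#' @param seed integer root seed (required). Independent child streams per
#'   (channel, gate) are derived deterministically from it.
#' @return An object of class `gamma_series`: complex `values`
#'   (sweeps x gates x channels), `tof_axis`, `timing`, `amplitude`, `noise`,
#'   `seed` and a `truth` list (`tof`, `xi_mean`, `xi_dia`, `xi_sys`,
#'   `beat_onsets`).
#' @export
simulate_gamma <- function(medium, timing, tof_gates, duration,
                           n_channels = 4, irf = NULL, pulsatility = NULL,
                           noise = noise_model(), seed) {
  stopifnot(inherits(medium, "medium_spec"), inherits(timing, "sweep_timing"),
            length(tof_gates) >= 1, all(tof_gates > 0), duration > 0,
            n_channels >= 1, inherits(noise, "noise_model"))
  if (missing(seed) || is.null(seed)) stop("a root seed is required")
  n <- as.integer(round(duration * timing$sweep_rate))
  dt <- timing$sweep_dt
  if (n < 4096) stop("duration must cover at least a few G1 blocks")

  # Amplitude profile: sqrt of the (IRF-convolved) TPSF at the gate centers,
  # evaluated on a fine grid and normalized to a unit maximum.
  fine <- seq(0, max(tof_gates) * 1.5, by = min(timing$tof_spacing / 2,
                                                min(tof_gates) / 4))
  tp <- tpsf_model(medium, fine, irf = irf)
  prof <- if (is.null(irf)) tp$raw else tp$convolved
  s_gate <- approx(fine, prof, xout = tof_gates, rule = 2)$y
  amplitude <- sqrt(s_gate / max(prof))

  xi_base <- decay_rate_profile(medium, tof_gates)
  if (any(xi_base < 0)) stop("negative decay rate: rho >= 1 is not allowed")

  beat_onsets <- NULL
  if (!is.null(pulsatility)) {
    stopifnot(inherits(pulsatility, "pulsatility_model"))
    set.seed(as.integer(.child_seed(seed, 0, 0)))
    ph <- .beat_phase(seq_len(n) * dt, pulsatility)
    w <- .cardiac_waveform(ph$phase)
    beat_onsets <- ph$onsets
  }

  values <- array(complex(real = 0, imaginary = 0),
                  dim = c(n, length(tof_gates), n_channels))
  xi_mean <- numeric(length(tof_gates))
  xi_dia <- xi_sys <- xi_base
  for (g in seq_along(tof_gates)) {
    if (is.null(pulsatility)) {
      rho <- exp(-xi_base[g] * dt)
      xi_mean[g] <- xi_base[g]
    } else {
      xi_dia[g] <- xi_base[g] * pulsatility$diastolic_scale
      xi_sys[g] <- xi_base[g] * pulsatility$systolic_scale
      xi_t <- xi_dia[g] + (xi_sys[g] - xi_dia[g]) * w
      rho <- exp(-xi_t * dt)
      xi_mean[g] <- mean(xi_t)
    }
    for (ch in seq_len(n_channels)) {
      set.seed(as.integer(.child_seed(seed, ch, g)))
      z <- .cx_ar1_stream(n, rho, amplitude[g])
      if (noise$gamma_noise_sd > 0) {
        s <- noise$gamma_noise_sd / sqrt(2)
        z <- z + complex(real = rnorm(n, 0, s), imaginary = rnorm(n, 0, s))
      }
      values[, g, ch] <- z
    }
  }
  structure(
    list(
      values = values, tof_axis = tof_gates, timing = timing,
      amplitude = amplitude, noise = noise, seed = seed,
      truth = list(tof = tof_gates, xi_mean = xi_mean, xi_dia = xi_dia,
                   xi_sys = xi_sys, beat_onsets = beat_onsets)
    ),
    class = "gamma_series"
  )
}

#' Synthesize raw interferograms from a Gamma stream
#'
#' Inverts the processing direction: each sweep's digitized samples are the
#' real part of a sum of complex tones, one per ToF bin, whose DFT bin mapping
#' matches [ifft_gamma()] so the round trip recovers the Gamma stream up to a
#' global complex scale.
#'
#' @param gamma a [simulate_gamma()] result.
#' @param timing a [sweep_timing()]; defaults to the one stored in `gamma`.
#' @param reference_amplitude reference-arm field amplitude multiplying every
#'   tone.
#' @param noise a [noise_model()] (only `adc_noise_sd` is used here).
#' @param seed integer seed for the ADC noise (required when
#'   `adc_noise_sd > 0`).
#' @return An object of class `sweep_frames`: real `samples`
#'   (sweeps x samples_per_sweep x channels) plus `timing` and the ToF bin
#'   mapping used.
#' @export
simulate_interferograms <- function(gamma, timing = gamma$timing,
                                    reference_amplitude = 1,
                                    noise = noise_model(), seed = NULL) {
  stopifnot(inherits(gamma, "gamma_series"), inherits(timing, "sweep_timing"))
  m <- timing$samples_per_sweep
  bins <- round(gamma$tof_axis / timing$tof_spacing)
  if (any(bins < 0) || any(bins > floor(m / 2))) {
    stop("ToF bin mapping falls outside the Nyquist range")
  }
  if (anyDuplicated(bins)) stop("ToF gates map to duplicate DFT bins")
  n <- dim(gamma$values)[1]
  n_ch <- dim(gamma$values)[3]
  # tone sign is paired with ifft_gamma's +i inverse transform so the round
  # trip recovers Gamma (not its conjugate) at the positive-delay bins
  tones <- exp(-2i * pi * outer(bins, 0:(m - 1)) / m)  # gates x m
  samples <- array(0, dim = c(n, m, n_ch))
  if (noise$adc_noise_sd > 0 && is.null(seed)) {
    stop("a seed is required when adc_noise_sd > 0")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (ch in seq_len(n_ch)) {
    g <- gamma$values[, , ch, drop = FALSE]
    dim(g) <- c(n, length(bins))
    y <- Re(g %*% tones) * reference_amplitude
    if (noise$adc_noise_sd > 0) {
      y <- y + matrix(rnorm(n * m, 0, noise$adc_noise_sd), n, m)
    }
    samples[, , ch] <- y
  }
  structure(
    list(samples = samples, timing = timing, bins = bins,
         tof_axis = gamma$tof_axis),
    class = "sweep_frames"
  )
}
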
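#' Recover the mutual-coherence (Gamma) function from raw sweeps
#'
#' Applies an inverse discrete Fourier transform to each (optionally tapered)
#' wavenumber-domain interferogram and keeps the nonnegative-delay bins,
#' yielding the complex, ToF-resolved optical field per sweep. The default
#' rectangular taper keeps the transform exact; a Hann taper is available for
#' sidelobe suppression.
#'
#' @param frames a `sweep_frames` object, or a numeric matrix
#'   (sweeps x samples) for a single channel.
#' @param timing a [sweep_timing()] (defaults to the one in `frames`).
#' @param window `"rectangular"` or `"hann"`.
#' @return A `gamma_frame` object: complex `values`
#'   (sweeps x ToF bins x channels) and `tof_axis` (s, spacing
#'   `timing$tof_spacing`, zero at bin 0 until anchored on an IRF).
#' @export
ifft_gamma <- function(frames, timing = NULL,
                       window = c("rectangular", "hann")) {
  window <- match.arg(window)
  if (inherits(frames, "sweep_frames")) {
    if (is.null(timing)) timing <- frames$timing
    samples <- frames$samples
  } else {
    samples <- frames
  }
  if (is.matrix(samples)) dim(samples) <- c(dim(samples), 1L)
  stopifnot(length(dim(samples)) == 3, dim(samples)[2] >= 2)
  m <- dim(samples)[2]
  if (!is.null(timing)) stopifnot(m == timing$samples_per_sweep)
  tof_spacing <- if (is.null(timing)) NA_real_ else timing$tof_spacing
  taper <- switch(window,
    rectangular = rep(1, m),
    hann = 0.5 - 0.5 * cos(2 * pi * seq_len(m) / m)
  )
  k <- floor(m / 2) + 1L  # nonnegative-delay bins
  n <- dim(samples)[1]
  n_ch <- dim(samples)[3]
  values <- array(complex(real = 0, imaginary = 0), dim = c(n, k, n_ch))
  for (ch in seq_len(n_ch)) {
    x <- samples[, , ch, drop = FALSE]
    dim(x) <- dim(samples)[1:2]
    x <- t(x) * taper  # m x n
    g <- mvfft(x, inverse = TRUE) / m
    values[, , ch] <- t(g[seq_len(k), , drop = FALSE])
  }
  structure(
    list(values = values, tof_axis = (seq_len(k) - 1) * tof_spacing,
         timing = timing),
    class = "gamma_frame"
  )
}

#' Average Gamma magnitudes into temporal point-spread functions
#'
#' The magnitude of the Gamma function is averaged per ToF bin over
#' consecutive blocks of `n_sweeps` sweeps (40,960 at the full sweep rate,
#' i.e. ~0.2 s of integration, a ~5 Hz TPSF rate).
#'
#' @param gamma a `gamma_frame` or `gamma_series` object.
#' @param n_sweeps sweeps per TPSF.
#' @return A `tpsf_record`: `magnitude` (blocks x ToF bins x channels),
#'   `tof_axis`, `n_sweeps` and `acquisition_time` (s).
#' @export
average_tpsf <- function(gamma, n_sweeps = 40960) {
  stopifnot(n_sweeps >= 1)
  v <- gamma$values
  n <- dim(v)[1]
  if (n < n_sweeps) {
    stop("fewer frames than n_sweeps: refusing to average a partial block")
  }
  n_blocks <- floor(n / n_sweeps)
  k <- dim(v)[2]
  n_ch <- dim(v)[3]
  mag <- array(0, dim = c(n_blocks, k, n_ch))
  for (b in seq_len(n_blocks)) {
    idx <- seq.int((b - 1) * n_sweeps + 1, b * n_sweeps)
    mag[b, , ] <- apply(Mod(v[idx, , , drop = FALSE]), c(2, 3), mean)
  }
  sweep_rate <- if (!is.null(gamma$timing)) gamma$timing$sweep_rate else NA
  structure(
    list(magnitude = mag, tof_axis = gamma$tof_axis, n_sweeps = n_sweeps,
         acquisition_time = n_sweeps / sweep_rate),
    class = "tpsf_record"
  )
}

#' Locate the ToF origin at the IRF peak
#'
#' Finds the sub-bin peak position of the instrument response function via
#' three-point parabolic interpolation around the discrete maximum. Downstream
#' ToF axes are shifted so this position is ToF = 0.
#'
#' @param irf an `irf_record` (or any list with `curve` and `tof_axis`).
#' @return Peak position in seconds on the IRF's own axis.
#' @export
locate_zero_tof <- function(irf) {
  y <- irf$curve
  n <- length(y)
  stopifnot(n >= 3)
  peaks <- which(y == max(y))
  i <- peaks[1]
  if (length(peaks) > 1) {
    warning("multiple equal maxima; using the earliest")
  }
  if (i == 1L || i == n) stop("IRF peak lies on the axis boundary")
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  frac <- if (denom == 0) 0 else 0.5 * (y[i - 1] - y[i + 1]) / denom
  dt <- irf$tof_axis[2] - irf$tof_axis[1]
  irf$tof_axis[i] + frac * dt
}

#' Full width at half maximum of an IRF curve
#'
#' Linear-interpolated width at half of the peak value.
#'
#' @param irf an `irf_record` (or list with `curve` and `tof_axis`).
#' @return FWHM in seconds.
#' @export
irf_fwhm <- function(irf) {
  y <- irf$curve
  t <- irf$tof_axis
  i <- which.max(y)
  half <- y[i] / 2
  left <- which(y[seq_len(i)] < half)
  right <- which(y[seq.int(i, length(y))] < half)
  if (length(left) == 0 || length(right) == 0) {
    stop("half level not crossed on both sides of the peak")
  }
  l <- max(left)  # last below-half index left of peak
  r <- i + min(right) - 1L  # first below-half index right of peak
  t_left <- t[l] + (half - y[l]) / (y[l + 1] - y[l]) * (t[l + 1] - t[l])
  t_right <- t[r - 1] + (half - y[r - 1]) / (y[r] - y[r - 1]) *
    (t[r] - t[r - 1])
  t_right - t_left
}

#' Blocked field autocorrelation G1 at one ToF gate
#'
#' For each block of `block` consecutive Gamma samples, advanced by `stride`,
#' computes the electric-field temporal autocorrelation
#' `G1(tau_j) = mean_n conj(Gamma(t_n)) Gamma(t_n+j)` with unbiased per-lag
#' pair counts. At the full-rate defaults (block 8192, stride 4096, 200 kHz)
#' the output rate is 48.8 Hz, conventionally labeled ~50 Hz. The gate is the
#' single ToF bin at the gate center; because of the finite IRF it represents
#' a window about one IRF FWHM wide.
#'
#' @param gamma a `gamma_series` or `gamma_frame` object.
#' @param tof_gate gate center, s; must coincide with a bin of the ToF axis.
#' @param block,stride block length and stride in sweeps.
#' @param max_lag largest lag (in sweep periods) retained; must be < `block`.
#'   The default 20 spans the 100 microsecond fit-window ceiling at the full
#'   sweep rate.
#' @return A `g1_record`: complex `values` (records x lags x channels) with
#'   lag 0 stored but flagged excluded, `lag_axis` (s), `tof_gate`, `times`
#'   (block centers, s), and `output_rate` (Hz).
#' @export
compute_g1 <- function(gamma, tof_gate, block = 8192, stride = 4096,
                       max_lag = 20) {
  stopifnot(block >= 2, stride >= 1, stride <= block)
  if (max_lag >= block) stop("max_lag must be smaller than block")
  dt_tof <- if (length(gamma$tof_axis) > 1) {
    min(diff(sort(gamma$tof_axis)))
  } else {
    gamma$tof_axis
  }
  gi <- which(abs(gamma$tof_axis - tof_gate) <= dt_tof / 2 + 1e-15)
  if (length(gi) == 0) stop("tof_gate does not lie on the ToF axis")
  gi <- gi[1]
  n <- dim(gamma$values)[1]
  if (n < block) stop("stream shorter than one block")
  n_ch <- dim(gamma$values)[3]
  dt <- gamma$timing$sweep_dt
  first <- .g1_blocked(gamma$values[, gi, 1], block, stride, max_lag)
  n_rec <- nrow(first)
  values <- array(complex(real = 0, imaginary = 0),
                  dim = c(n_rec, max_lag + 1L, n_ch))
  values[, , 1] <- first
  if (n_ch > 1) {
    for (ch in 2:n_ch) {
      values[, , ch] <- .g1_blocked(gamma$values[, gi, ch], block, stride,
                                    max_lag)
    }
  }
  offsets <- (seq_len(n_rec) - 1) * stride
  structure(
    list(
      values = values,
      lag_axis = (0:max_lag) * dt,
      tof_gate = gamma$tof_axis[gi],
      times = (offsets + block / 2) * dt,
      output_rate = gamma$timing$sweep_rate / stride,
      block = block, stride = stride,
      zero_lag_excluded = TRUE
    ),
    class = "g1_record"
  )
}
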
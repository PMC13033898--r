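#' Normalize G1 at the first autocorrelation lag
#'
#' For consistency across ToF gates, each record is normalized by its value at
#' `tau1`, the first lag (one sweep period, 5 microseconds at the full sweep
#' rate): `g1(tau) = G1(tau) / G1(tau1)`. The zero-lag value is dropped from
#' the analysis; gates with `|G1(tau1)| = 0` are flagged invalid.
#'
#' @param g1 a `g1_record`.
#' @return A `normalized_g1` object: complex `values` (records x lags 1..L x
#'   channels), `tau_axis`, `tau1`, `invalid` (records x channels logical),
#'   plus timing metadata carried over.
#' @export
normalize_g1 <- function(g1) {
  stopifnot(inherits(g1, "g1_record"))
  if (length(g1$lag_axis) < 2) stop("lag axis must include tau1")
  v <- g1$values
  n_rec <- dim(v)[1]
  n_ch <- dim(v)[3]
  denom <- v[, 2, , drop = FALSE]
  dim(denom) <- c(n_rec, n_ch)
  invalid <- Mod(denom) == 0 | !is.finite(Mod(denom))
  out <- v[, -1, , drop = FALSE]
  for (ch in seq_len(n_ch)) {
    d <- denom[, ch]
    d[invalid[, ch]] <- NA_complex_
    out[, , ch] <- out[, , ch, drop = FALSE] / d  # recycles along lags
  }
  structure(
    list(
      values = out, tau_axis = g1$lag_axis[-1], tau1 = g1$lag_axis[2],
      invalid = invalid, tof_gate = g1$tof_gate, times = g1$times,
      output_rate = g1$output_rate
    ),
    class = "normalized_g1"
  )
}

#' Select autocorrelation lags for the decay fit
#'
#' The fit uses the larger of two sets: lags with `|g1| > 0.5` and
#' `tau < tau_max` (strict inequalities), or the first five lags. At the full
#' sweep rate `tau_max` is 100 microseconds; desk-scale presets scale it with
#' the lag unit.
#'
#' @param g1_mag magnitudes of the normalized g1 at the lags in `tau`.
#' @param tau lag times, s (>= 5 values).
#' @param g1_min magnitude threshold (default 0.5).
#' @param tau_max lag-time ceiling, s (default 100e-6).
#' @return Integer indices into `tau` of the selected fit points.
#' @export
select_fit_points <- function(g1_mag, tau, g1_min = 0.5, tau_max = 100e-6) {
  if (length(tau) < 5) stop("at least 5 lags are required")
  stopifnot(length(g1_mag) == length(tau))
  keep <- which(g1_mag > g1_min & tau < tau_max)
  if (length(keep) < 5) keep <- seq_len(5)
  keep
}

#' Fit the single-exponential g1 decay rate
#'
#' Nonlinear least squares fit of `|g1(tau)|` to `exp(-xi (tau - tau1))`,
#' anchored at the normalization point `g1(tau1) = 1`. Initialization comes
#' from the log-linear slope; the decay rate is constrained nonnegative and
#' clipped (with a flag) if the unconstrained optimum would be negative.
#'
#' @param g1_mag magnitudes of normalized g1 at the lags in `tau`.
#' @param tau lag times, s.
#' @param tau1 normalization lag, s (default `tau[1]`).
#' @param points indices of fit points; defaults to [select_fit_points()]
#'   with its default truncation rule.
#' @param ... passed to [select_fit_points()] when `points` is `NULL`.
#' @return A list: `xi` (Hz), `residual` (RMS of fit residuals), `n_points`,
#'   `clipped`, `valid`.
#' @export
fit_decay <- function(g1_mag, tau, tau1 = tau[1], points = NULL, ...) {
  if (any(!is.finite(g1_mag))) {
    return(list(xi = NA_real_, residual = NA_real_, n_points = 0L,
                clipped = FALSE, valid = FALSE))
  }
  if (is.null(points)) points <- select_fit_points(g1_mag, tau, ...)
  if (length(points) < 2) stop("at least 2 fit points are required")
  y <- g1_mag[points]
  x <- tau[points] - tau1
  slope <- sum(x * log(pmax(y, 1e-12))) / sum(x^2)
  xi0 <- max(0, -slope)
  clipped <- FALSE
  # port can report false convergence on noisy records whose optimum is flat;
  # the returned coefficient is still the best found, so warnings are muted
  fit <- tryCatch(
    suppressWarnings(
      nls(y ~ exp(-xi * x), start = list(xi = xi0), algorithm = "port",
          lower = 0, control = list(warnOnly = TRUE))
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    xi <- xi0
    res <- sqrt(mean((y - exp(-xi * x))^2))
    clipped <- slope > 0
  } else {
    xi <- unname(coef(fit)[["xi"]])
    res <- sqrt(mean(stats::resid(fit)^2))
    clipped <- xi == 0 && slope > 0
  }
  list(xi = xi, residual = res, n_points = length(points),
       clipped = clipped, valid = TRUE)
}

#' Combine channels by averaging normalized g1 magnitudes
#'
#' Per-lag mean of `|g1|` over valid channels (invalid gates excluded),
#' applied after normalization and before fitting.
#'
#' @param norm_g1 a [normalize_g1()] result.
#' @return A `combined_g1` object: `magnitude` (records x lags), `tau_axis`,
#'   `tau1` and timing metadata. Records with no valid channel are `NA`.
#' @export
combine_channels <- function(norm_g1) {
  stopifnot(inherits(norm_g1, "normalized_g1"))
  n_ch <- dim(norm_g1$values)[3]
  if (all(norm_g1$invalid)) stop("no valid channels to combine")
  mag <- Mod(norm_g1$values)
  for (ch in seq_len(n_ch)) {
    bad <- norm_g1$invalid[, ch]
    if (any(bad)) mag[bad, , ch] <- NA_real_
  }
  combined <- apply(mag, c(1, 2), mean, na.rm = TRUE)
  combined[is.nan(combined)] <- NA_real_
  structure(
    list(magnitude = combined, tau_axis = norm_g1$tau_axis,
         tau1 = norm_g1$tau1, tof_gate = norm_g1$tof_gate,
         times = norm_g1$times, output_rate = norm_g1$output_rate),
    class = "combined_g1"
  )
}

#' Fit decay rates for every record of a combined g1 series
#'
#' @param combined a [combine_channels()] result (or a `normalized_g1`, in
#'   which case channels are combined first).
#' @param g1_min,tau_max truncation rule passed to [select_fit_points()].
#' @return A `decay_series`: `xi` (Hz per record), `times`, `output_rate`,
#'   `tof_gate`, `residual`, `n_points`, `clipped`, `valid`.
#' @export
fit_decay_series <- function(combined, g1_min = 0.5, tau_max = 100e-6) {
  if (inherits(combined, "normalized_g1")) {
    combined <- combine_channels(combined)
  }
  stopifnot(inherits(combined, "combined_g1"))
  mag <- combined$magnitude
  n_rec <- nrow(mag)
  xi <- residual <- numeric(n_rec)
  n_points <- integer(n_rec)
  clipped <- valid <- logical(n_rec)
  for (r in seq_len(n_rec)) {
    f <- fit_decay(mag[r, ], combined$tau_axis, tau1 = combined$tau1,
                   g1_min = g1_min, tau_max = tau_max)
    xi[r] <- f$xi
    residual[r] <- f$residual
    n_points[r] <- f$n_points
    clipped[r] <- f$clipped
    valid[r] <- f$valid
  }
  structure(
    list(xi = xi, times = combined$times, output_rate = combined$output_rate,
         tof_gate = combined$tof_gate, residual = residual,
         n_points = n_points, clipped = clipped, valid = valid),
    class = "decay_series"
  )
}

#' Relative blood flow index
#'
#' `rBFi(t) = xi(t) / <xi(t0)>`, the decay rate normalized by its temporal
#' mean over a baseline window, enabling comparison across subjects,
#' protocols and ToF gates. Unit changes in `xi` cancel.
#'
#' @param xi decay-rate series (numeric vector or `decay_series`).
#' @param times sample times, s (taken from a `decay_series` automatically).
#' @param baseline_window `c(start, end)` time range of the baseline, s.
#' @return Numeric rBFi series with attribute `baseline_mean` (Hz).
#' @export
rbfi <- function(xi, times = NULL, baseline_window) {
  if (inherits(xi, "decay_series")) {
    if (is.null(times)) times <- xi$times
    xi <- xi$xi
  }
  stopifnot(length(xi) == length(times), length(baseline_window) == 2)
  idx <- times >= baseline_window[1] & times <= baseline_window[2]
  if (!any(idx)) stop("baseline window contains no samples")
  base <- mean(xi[idx], na.rm = TRUE)
  if (!is.finite(base) || base <= 0) stop("baseline mean must be positive")
  structure(xi / base, baseline_mean = base)
}

#' Zero-phase low-pass filter for rBFi series
#'
#' Attenuates cardiac pulsatility with a forward-backward Butterworth filter
#' (unit DC gain, no phase distortion). The default 0.5 Hz cutoff passes
#' hemodynamic-response-scale changes while suppressing the ~1 Hz cardiac
#' band by more than 20 dB.
#'
#' @param x numeric series.
#' @param rate sampling rate, Hz (must exceed twice the cutoff).
#' @param cutoff cutoff frequency, Hz.
#' @param order Butterworth order (applied twice via filtfilt).
#' @return Filtered series.
#' @export
lowpass_rbfi <- function(x, rate, cutoff = 0.5, order = 4) {
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  .filtfilt_padded(bf, x, n_pad = ceiling(3 * rate / cutoff))
}

# Zero-phase filtering with mean removal and reflected end padding, so a
# constant passes exactly and edge transients do not leak into the series.
# `restore_mean` is for unit-DC-gain (low-pass) use; band-pass callers keep
# the zero-mean output.
.filtfilt_padded <- function(bf, x, n_pad, restore_mean = TRUE) {
  n <- length(x)
  n_pad <- min(n - 1, n_pad)
  mu <- mean(x)
  xc <- x - mu
  xp <- c(2 * xc[1] - rev(xc[seq.int(2, n_pad + 1)]),
          xc,
          2 * xc[n] - rev(xc[seq.int(n - n_pad, n - 1)]))
  y <- as.numeric(signal::filtfilt(bf, xp))
  y <- y[seq.int(n_pad + 1, n_pad + n)]
  if (restore_mean) y + mu else y
}
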
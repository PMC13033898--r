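#' Sliding-window gradient of decay rate versus ToF
#'
#' Ordinary least-squares slope (and slope standard error) of the decay rate
#' within a window of consecutive ToF points, advanced one bin at a time.
#' The default five-point window is the smallest that gives stable slope
#' estimates while preserving local structure.
#'
#' @param xi decay rates per ToF point (Hz or kHz; units carry into slopes).
#' @param tof ToF values, s (same length, increasing).
#' @param window window width in points (>= 3).
#' @return A `gradient_scan` data frame: `start_tof`, `end_tof`, `slope`,
#'   `se`, `ok` (FALSE for windows skipped over non-finite input).
#' @export
sliding_gradient <- function(xi, tof, window = 5) {
  stopifnot(length(xi) == length(tof), window >= 3)
  if (length(xi) < window) stop("need at least `window` points")
  n_win <- length(xi) - window + 1L
  out <- data.frame(
    start_tof = numeric(n_win), end_tof = numeric(n_win),
    slope = numeric(n_win), se = numeric(n_win), ok = logical(n_win)
  )
  for (w in seq_len(n_win)) {
    idx <- seq.int(w, w + window - 1L)
    x <- tof[idx]
    y <- xi[idx]
    out$start_tof[w] <- x[1]
    out$end_tof[w] <- x[window]
    if (any(!is.finite(y))) {
      out[w, c("slope", "se")] <- NA_real_
      out$ok[w] <- FALSE
      next
    }
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    b <- sum(xc * y) / sxx
    a <- mean(y) - b * mean(x)
    rss <- sum((y - a - b * x)^2)
    out$slope[w] <- b
    out$se[w] <- sqrt(rss / (window - 2) / sxx)
    out$ok[w] <- TRUE
  }
  class(out) <- c("gradient_scan", "data.frame")
  out
}

#' Depth-sensitivity onset from paired gradient scans
#'
#' Compares the windowed ToF gradients of a test condition against a
#' reference condition with per-window z-tests,
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)`, and reports the last ToF point of
#' the earliest window where `|z|` exceeds the threshold -- the ToF at which
#' the measurement first becomes sensitive to the condition difference (e.g.
#' deep-layer flow).
#'
#' @param scan_condition,scan_reference [sliding_gradient()] results on
#'   identical window grids.
#' @param z_threshold flag threshold on `|z|` (default 10).
#' @return A list: `onset_tof` (s; `NA` if no window is flagged), `z` per
#'   window (`NA` where both standard errors vanish or a window was skipped),
#'   `flagged` (logical per window).
#' @export
sensitivity_onset <- function(scan_condition, scan_reference,
                              z_threshold = 10) {
  stopifnot(nrow(scan_condition) == nrow(scan_reference))
  if (any(abs(scan_condition$start_tof - scan_reference$start_tof) >
            1e-15 + 1e-9 * abs(scan_condition$start_tof))) {
    stop("window grids are not aligned")
  }
  se2 <- scan_condition$se^2 + scan_reference$se^2
  z <- (scan_condition$slope - scan_reference$slope) / sqrt(se2)
  z[se2 == 0] <- NA_real_
  z[!scan_condition$ok | !scan_reference$ok] <- NA_real_
  flagged <- !is.na(z) & abs(z) > z_threshold
  onset <- if (any(flagged)) {
    scan_condition$end_tof[which(flagged)[1]]
  } else {
    NA_real_
  }
  list(onset_tof = onset, z = z, flagged = flagged)
}

#' Piecewise-linear fit of decay rate versus ToF
#'
#' Independent OLS lines fitted to the points at or before and strictly after
#' the breakpoint, as used to describe a gradient change where a deeper layer
#' begins to influence the signal.
#'
#' @param xi decay rates.
#' @param tof ToF values, s.
#' @param breakpoint ToF of the change point, s; must leave >= 2 points on
#'   each side.
#' @return A list: `slope_before`, `slope_after`, `intercept_before`,
#'   `intercept_after`, `rss` (summed residual sum of squares), `breakpoint`.
#' @export
piecewise_fit <- function(xi, tof, breakpoint) {
  stopifnot(length(xi) == length(tof))
  left <- tof <= breakpoint
  right <- !left
  if (sum(left) < 2 || sum(right) < 2) {
    stop("breakpoint must leave at least 2 points on each side")
  }
  f1 <- lm(xi[left] ~ tof[left])
  f2 <- lm(xi[right] ~ tof[right])
  list(
    slope_before = unname(coef(f1)[2]), slope_after = unname(coef(f2)[2]),
    intercept_before = unname(coef(f1)[1]),
    intercept_after = unname(coef(f2)[1]),
    rss = sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2),
    breakpoint = breakpoint
  )
}

#' Relative change in decay rate between two flow conditions
#'
#' `100 * (xi_high - xi_low) / xi_low`, the percent change used to quantify
#' sensitivity to deep-layer flow at a given ToF.
#'
#' @param xi_low,xi_high decay rates in the low- and high-flow conditions
#'   (same units; both > 0 for `xi_low`).
#' @return Percent change.
#' @export
relative_deep_sensitivity <- function(xi_low, xi_high) {
  if (any(xi_low <= 0)) stop("xi_low must be positive")
  100 * (xi_high - xi_low) / xi_low
}

#' Long-duration drift test on windowed means
#'
#' Splits the series into nonoverlapping windows (default 30 min), computes
#' the windowed mean, and regresses the means on the window center times. The
#' two-sided t-test on the regression slope quantifies drift.
#'
#' @param xi decay-rate series (vector, or matrix with one column per ToF
#'   gate).
#' @param times sample times, s.
#' @param window window length, s (default 1800).
#' @return A `drift_report` data frame, one row per gate: `slope_per_hour`
#'   (input units per hour), `se_per_hour`, `p_value`, `n_windows`.
#' @export
drift_test <- function(xi, times, window = 1800) {
  if (is.vector(xi)) xi <- matrix(xi, ncol = 1)
  stopifnot(nrow(xi) == length(times), window > 0)
  t0 <- min(times)
  span <- max(times) - t0
  n_win <- floor(span / window)
  if (n_win < 2) stop("need at least 2 full windows")
  bin <- floor((times - t0) / window) + 1L
  keep <- bin <= n_win
  out <- data.frame(
    gate = seq_len(ncol(xi)), slope_per_hour = NA_real_,
    se_per_hour = NA_real_, p_value = NA_real_, n_windows = n_win
  )
  centers <- (seq_len(n_win) - 0.5) * window + t0
  for (g in seq_len(ncol(xi))) {
    means <- tapply(xi[keep, g], bin[keep], mean)
    fit <- summary(lm(means ~ centers))$coefficients
    out$slope_per_hour[g] <- fit[2, 1] * 3600
    out$se_per_hour[g] <- fit[2, 2] * 3600
    out$p_value[g] <- fit[2, 4]
  }
  class(out) <- c("drift_report", "data.frame")
  out
}

#' Coefficient of variation of the decay rate
#'
#' `CoV = 100 * sigma / xi`; the effective CoV replaces `sigma` with
#' `sigma / sqrt(n_avg)` to account for temporal averaging over `n_avg`
#' samples (e.g. a rolling ten-pulse window, or 50 samples when reporting at
#' 1 Hz from a ~50 Hz series).
#'
#' @param sigma_khz decay-rate standard deviation, kHz (>= 0).
#' @param xi_khz reference decay rate, kHz (> 0).
#' @param n_avg number of samples averaged (>= 1).
#' @return A list: `cov_percent`, `effective_cov_percent`, plus the inputs.
#' @export
cov_metrics <- function(sigma_khz, xi_khz, n_avg = 1) {
  if (any(xi_khz <= 0)) stop("xi_khz must be positive")
  stopifnot(sigma_khz >= 0, n_avg >= 1)
  list(
    cov_percent = 100 * sigma_khz / xi_khz,
    effective_cov_percent = 100 * (sigma_khz / sqrt(n_avg)) / xi_khz,
    sigma_khz = sigma_khz, xi_khz = xi_khz, n_avg = n_avg
  )
}

#' Sample size for estimating a mean decay rate
#'
#' Standard normal-approximation sample-size formula:
#' `n = ceil((z * sigma / margin)^2)` with `z` the two-sided normal quantile
#' at the requested confidence.
#'
#' @param sigma_khz decay-rate standard deviation, kHz.
#' @param margin_khz half-width of the desired confidence interval, kHz
#'   (> 0).
#' @param confidence confidence level in (0, 1).
#' @return Required number of samples (integer).
#' @export
sample_size <- function(sigma_khz, margin_khz, confidence = 0.95) {
  if (margin_khz <= 0) stop("margin must be positive")
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must lie in (0, 1)")
  }
  z <- qnorm((1 + confidence) / 2)
  as.integer(ceiling((z * sigma_khz / margin_khz)^2))
}

#' Stimulus-minus-control functional response statistics
#'
#' For each subject, each trial's rBFi is renormalized to the mean of the
#' 10 s preceding trial onset; the trial response is the mean renormalized
#' rBFi over the post-onset response window (default 5--20 s). The subject
#' value is the mean stimulus response minus the mean control response, in
#' percent; the group distribution is tested against zero with a two-tailed
#' one-sample t-test.
#'
#' @param subjects a list, one element per subject, each a list with `rbfi`
#'   (numeric series, low-pass filtered upstream), `stim_onsets` and
#'   `control_onsets` (s).
#' @param rate sampling rate of the rBFi series, Hz.
#' @param baseline baseline length before onset, s.
#' @param window `c(start, end)` of the response window after onset, s.
#' @return A list: `per_subject` (percent differences), `mean`, `sem`,
#'   `p_value`, `n_dropped` (trials extending beyond a recording).
#' @export
trial_response <- function(subjects, rate, baseline = 10,
                           window = c(5, 20)) {
  stopifnot(length(subjects) >= 1, rate > 0, baseline > 0,
            length(window) == 2, window[2] > window[1])
  n_dropped <- 0L
  trial_mean <- function(x, onset) {
    i_base <- seq.int(floor((onset - baseline) * rate) + 1,
                      floor(onset * rate))
    i_win <- seq.int(floor((onset + window[1]) * rate) + 1,
                     floor((onset + window[2]) * rate))
    if (min(i_base) < 1 || max(i_win) > length(x)) return(NA_real_)
    mean(x[i_win]) / mean(x[i_base])
  }
  per_subject <- vapply(subjects, function(s) {
    stopifnot(length(s$stim_onsets) >= 1, length(s$control_onsets) >= 1)
    stim <- vapply(s$stim_onsets, trial_mean, numeric(1), x = s$rbfi)
    ctrl <- vapply(s$control_onsets, trial_mean, numeric(1), x = s$rbfi)
    n_dropped <<- n_dropped + sum(is.na(stim)) + sum(is.na(ctrl))
    100 * (mean(stim, na.rm = TRUE) - mean(ctrl, na.rm = TRUE))
  }, numeric(1))
  tt <- if (length(per_subject) > 1) {
    t.test(per_subject, mu = 0, alternative = "two.sided")
  } else {
    NULL
  }
  list(
    per_subject = per_subject, mean = mean(per_subject),
    sem = if (length(per_subject) > 1) {
      sd(per_subject) / sqrt(length(per_subject))
    } else {
      NA_real_
    },
    p_value = if (is.null(tt)) NA_real_ else tt$p.value,
    n_dropped = n_dropped
  )
}
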
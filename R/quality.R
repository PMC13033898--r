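#' Detect cardiac beats in an rBFi series
#'
#' Band-passes the series to the cardiac band (0.5--5 Hz, zero-phase
#' Butterworth) and takes beat onsets at the diastolic troughs, enforcing a
#' refractory period. Troughs shallower than a quarter of the band-passed
#' signal's standard deviation are ignored.
#'
#' @param x rBFi series (>= 10 s long).
#' @param rate sampling rate, Hz (>= 10).
#' @param band cardiac band edges, Hz.
#' @param refractory minimum beat separation, s.
#' @return Beat onset times, s.
#' @export
detect_beats <- function(x, rate, band = c(0.5, 5), refractory = 0.3) {
  if (rate < 10) stop("sampling rate must be at least 10 Hz")
  if (length(x) / rate < 10) stop("series must be at least 10 s long")
  if (band[2] >= rate / 2) band[2] <- 0.45 * rate
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  y <- .filtfilt_padded(bf, x, n_pad = ceiling(3 * rate / band[1]),
                        restore_mean = FALSE)
  if (sd(y) <= 1e-8 * max(sd(x), .Machine$double.eps)) {
    stop("no pulsatile component: fewer than 2 beats detectable")
  }
  thr <- -0.25 * sd(y)
  n <- length(y)
  cand <- which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
  cand <- cand[y[cand] < thr]
  if (length(cand) >= 2) {
    # enforce refractory period, keeping the deeper trough on conflict
    keep <- cand[1]
    for (i in cand[-1]) {
      last <- keep[length(keep)]
      if ((i - last) / rate >= refractory) {
        keep <- c(keep, i)
      } else if (y[i] < y[last]) {
        keep[length(keep)] <- i
      }
    }
    cand <- keep
  }
  if (length(cand) < 2) stop("fewer than 2 beats detected")
  # refine each trough to the raw-signal minimum nearby: the band-pass
  # reshapes asymmetric waveforms and shifts their minima slightly early
  half <- max(1L, as.integer(round(0.15 * rate)))
  cand <- vapply(cand, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    lo - 1L + which.min(x[lo:hi])
  }, integer(1))
  cand <- sort(unique(cand))
  (cand - 1) / rate
}

#' Segment consecutive cardiac pulses into a common-length matrix
#'
#' Cuts the series at consecutive beat onsets, linearly resamples each pulse
#' to a common axis of `n_resample` points, then z-scores each pulse, so each
#' row has mean 0 and variance 1 regardless of beat length or signal scale.
#'
#' @param x rBFi series.
#' @param beat_times beat onset times, s (e.g. from [detect_beats()] or the
#'   simulator's ground truth).
#' @param rate sampling rate, Hz.
#' @param n_pulses number of consecutive pulses (default 10).
#' @param n_resample samples per resampled pulse.
#' @param start_beat index of the first beat to use.
#' @return A `pulse_matrix`: `pulses` (rows = pulses), `beat_times`,
#'   `n_skipped` (pulses dropped for having < 3 samples).
#' @export
segment_pulses <- function(x, beat_times, rate, n_pulses = 10,
                           n_resample = 100, start_beat = 1) {
  if (length(beat_times) < start_beat + n_pulses) {
    stop("need at least n_pulses + 1 beats")
  }
  rows <- list()
  used <- numeric(0)
  n_skipped <- 0L
  for (i in seq.int(start_beat, start_beat + n_pulses - 1)) {
    i0 <- floor(beat_times[i] * rate) + 1L
    i1 <- floor(beat_times[i + 1] * rate)
    if (i1 > length(x)) break
    seg <- x[i0:i1]
    if (length(seg) < 3) {
      n_skipped <- n_skipped + 1L
      next
    }
    res <- approx(seq(0, 1, length.out = length(seg)), seg,
                  xout = seq(0, 1, length.out = n_resample))$y
    s <- sd(res)
    rows[[length(rows) + 1]] <- if (s > 0) (res - mean(res)) / s else res * 0
    used <- c(used, beat_times[i])
  }
  if (length(rows) < 2) stop("fewer than 2 usable pulses")
  structure(
    list(pulses = do.call(rbind, rows), beat_times = used,
         n_skipped = n_skipped),
    class = "pulse_matrix"
  )
}

#' Pulse variance ratio (PVR)
#'
#' Quality statistic for a train of z-scored, resampled cardiac pulses:
#' `PVR = 1 - <sigma2_across> / <sigma2_within>`, where `<sigma2_within>` is
#' the mean over pulses of each pulse's variance across time and
#' `<sigma2_across>` is the mean over time samples of the variance across
#' pulses. A train of perfectly identical pulses gives PVR = 1; pure noise
#' gives PVR near 0 and can go negative. Per-pulse z-scoring makes the value
#' invariant to any common affine rescaling of the input.
#'
#' @param m a `pulse_matrix` or a numeric matrix (pulses x samples, >= 2 of
#'   each).
#' @return A list: `pvr` (NA with `undefined = TRUE` if the within-pulse
#'   variance vanishes), `sigma2_within`, `sigma2_across`, `undefined`.
#' @export
pvr <- function(m) {
  if (inherits(m, "pulse_matrix")) m <- m$pulses
  stopifnot(is.matrix(m), nrow(m) >= 2, ncol(m) >= 2)
  s2_within <- mean(apply(m, 1, var))
  s2_across <- mean(apply(m, 2, var))
  if (s2_within == 0) {
    return(list(pvr = NA_real_, sigma2_within = 0,
                sigma2_across = s2_across, undefined = TRUE))
  }
  list(pvr = 1 - s2_across / s2_within, sigma2_within = s2_within,
       sigma2_across = s2_across, undefined = FALSE)
}

#' Median PVR over rolling pulse windows
#'
#' Computes the PVR over every rolling window of `n_pulses` consecutive
#' pulses and reports the median, since a recording contains many candidate
#' pulse trains.
#'
#' @inheritParams segment_pulses
#' @param beat_times optional beat onsets; detected with [detect_beats()]
#'   when `NULL`.
#' @return A list: `pvr_median`, `pvr_windows`, `n_windows`, `beat_times`.
#' @export
rolling_pvr <- function(x, rate, beat_times = NULL, n_pulses = 10,
                        n_resample = 100) {
  if (is.null(beat_times)) beat_times <- detect_beats(x, rate)
  n_win <- length(beat_times) - n_pulses
  if (n_win < 1) stop("not enough beats for one pulse train")
  vals <- vapply(seq_len(n_win), function(s) {
    pm <- segment_pulses(x, beat_times, rate, n_pulses = n_pulses,
                         n_resample = n_resample, start_beat = s)
    pvr(pm)$pvr
  }, numeric(1))
  list(pvr_median = stats::median(vals, na.rm = TRUE), pvr_windows = vals,
       n_windows = n_win, beat_times = beat_times)
}

#' Corner ToF: the latest gate with high-quality pulsatile signal
#'
#' The maximum ToF gate whose PVR exceeds the threshold (default 0.6). For
#' non-monotone PVR profiles the default takes the literal maximum qualifying
#' gate; `rule = "contiguous"` instead returns the last gate of the
#' contiguous qualifying prefix.
#'
#' @param pvr_by_gate PVR value per gate.
#' @param tof gate ToF centers, s (same length).
#' @param threshold PVR threshold.
#' @param rule `"max"` or `"contiguous"`.
#' @return The corner ToF in seconds, or `NA` (flagged via attribute
#'   `undefined`) if no gate qualifies.
#' @export
corner_tof <- function(pvr_by_gate, tof, threshold = 0.6,
                       rule = c("max", "contiguous")) {
  rule <- match.arg(rule)
  stopifnot(length(pvr_by_gate) == length(tof), length(tof) >= 1)
  ok <- which(pvr_by_gate > threshold)
  if (length(ok) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  if (rule == "max") {
    tof[max(ok)]
  } else {
    qual <- seq_along(tof) %in% ok
    prefix <- which(cumsum(qual) == seq_along(tof) & qual)
    if (length(prefix) == 0) structure(NA_real_, undefined = TRUE) else
      tof[max(prefix)]
  }
}
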
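test_that("sliding gradients match the closed-form OLS oracle", {
  set.seed(1)
  tof <- seq(0.1, 1.2, by = 0.05) * 1e-9
  xi <- 25e3 * tof / 1e-9 + rnorm(length(tof), 0, 300)
  scan <- sliding_gradient(xi, tof)         # default five-point window
  expect_equal(nrow(scan), length(tof) - 4)
  for (w in c(1, 5, nrow(scan))) {
    idx <- seq.int(w, w + 4)
    o <- ols_slope_se(tof[idx], xi[idx])
    expect_equal(scan$slope[w], o$slope, tolerance = 1e-10)
    expect_equal(scan$se[w], o$se, tolerance = 1e-10)
  }
  # exactly linear profile: every slope equals the line slope, SEs ~ 0
  lin <- sliding_gradient(40e3 * tof / 1e-9 + 2e3, tof)
  expect_equal(lin$slope, rep(40e3 / 1e-9, nrow(lin)), tolerance = 1e-9)
  expect_true(all(lin$se < 1e-3 * abs(lin$slope)))
  # non-finite points skip their windows with a flag
  xi_bad <- xi
  xi_bad[3] <- NA
  scan_bad <- sliding_gradient(xi_bad, tof)
  expect_false(any(scan_bad$ok[1:3]))
  expect_true(all(scan_bad$ok[-(1:3)]))
})

test_that("sensitivity onset flags the earliest window containing the change", {
  dt <- 0.05e-9
  tof <- seq(0.1e-9, 1.2e-9, by = dt)
  slope_ref <- 25e3 / 1e-9
  change <- 0.4e-9
  extra <- 40e3 / 1e-9
  set.seed(2)
  noise_sd <- 200
  ref <- slope_ref * tof + rnorm(length(tof), 0, noise_sd)
  cond <- slope_ref * tof + extra * pmax(0, tof - change) +
    rnorm(length(tof), 0, noise_sd)
  s_ref <- sliding_gradient(ref, tof)
  s_cond <- sliding_gradient(cond, tof)
  on <- sensitivity_onset(s_cond, s_ref)

  # brute-force oracle: recompute every window's z from the closed-form OLS
  z_oracle <- vapply(seq_len(nrow(s_ref)), function(w) {
    idx <- seq.int(w, w + 4)
    a <- ols_slope_se(tof[idx], cond[idx])
    b <- ols_slope_se(tof[idx], ref[idx])
    (a$slope - b$slope) / sqrt(a$se^2 + b$se^2)
  }, numeric(1))
  first <- which(abs(z_oracle) > 10)[1]
  expect_equal(on$onset_tof, s_cond$end_tof[first])

  # windows straddling the kink carry the misfit in their slope SE, so the
  # earliest measurably different window is the first lying wholly on the
  # changed segment: it starts at the change point and ends 4 bins later
  expect_equal(s_cond$start_tof[first], change, tolerance = 1e-12)
  expect_equal(on$onset_tof, change + 4 * dt, tolerance = 1e-12)

  # identical scans: nothing flagged, onset undefined
  none <- sensitivity_onset(s_ref, s_ref)
  expect_true(is.na(none$onset_tof))
  expect_error(sensitivity_onset(s_cond, s_ref[-1, ]), "")
})

test_that("sensitivity onset is translation-equivariant and scale-invariant", {
  dt <- 0.05e-9
  tof <- seq(0.1e-9, 1.2e-9, by = dt)
  set.seed(3)
  ref <- 25e3 / 1e-9 * tof + rnorm(length(tof), 0, 200)
  cond <- ref + 40e3 / 1e-9 * pmax(0, tof - 0.4e-9)
  base <- sensitivity_onset(sliding_gradient(cond, tof),
                            sliding_gradient(ref, tof))
  shift <- 0.2e-9
  shifted <- sensitivity_onset(sliding_gradient(cond, tof + shift),
                               sliding_gradient(ref, tof + shift))
  expect_equal(shifted$onset_tof, base$onset_tof + shift, tolerance = 1e-15)
  scaled <- sensitivity_onset(sliding_gradient(3.7 * cond, tof),
                              sliding_gradient(3.7 * ref, tof))
  expect_equal(scaled$onset_tof, base$onset_tof)
  expect_equal(scaled$z, base$z, tolerance = 1e-9)
})

test_that("piecewise fits recover two-segment lines and beat a single line", {
  tof <- seq(0.1, 1.2, by = 0.05) * 1e-9
  xi <- ifelse(tof <= 0.4e-9, 10e3 + 20e3 / 1e-9 * tof,
               10e3 + 20e3 / 1e-9 * 0.4e-9 + 55e3 / 1e-9 * (tof - 0.4e-9))
  pw <- piecewise_fit(xi, tof, breakpoint = 0.4e-9)
  expect_equal(pw$slope_before, 20e3 / 1e-9, tolerance = 1e-9)
  expect_equal(pw$slope_after, 55e3 / 1e-9, tolerance = 1e-9)
  expect_lt(pw$rss, 1e-6)

  set.seed(4)
  noisy <- xi + rnorm(length(xi), 0, 500)
  pw_n <- piecewise_fit(noisy, tof, breakpoint = 0.4e-9)
  single_rss <- sum(resid(lm(noisy ~ tof))^2)
  expect_lte(pw_n$rss, single_rss)  # nested-model inequality
  expect_error(piecewise_fit(xi, tof, breakpoint = 1.3e-9), "each side")
})

test_that("relative deep sensitivity reproduces the printed flow contrasts", {
  expect_equal(relative_deep_sensitivity(25, 40), 60)
  expect_equal(relative_deep_sensitivity(49, 66), 35, tolerance = 0.01)
  expect_equal(relative_deep_sensitivity(30, 30), 0)
  expect_error(relative_deep_sensitivity(0, 40), "positive")
})

test_that("drift regression recovers an injected trend and validates input", {
  rate <- 1 / 30  # one sample every 30 s
  times <- seq(0, 24 * 3600, by = 30)
  trend <- 1e3 / 3600  # 1 kHz per hour, in Hz/s
  xi <- 28e3 + trend * times
  # (suppressed warning: summary.lm flags the essentially perfect fit)
  rep <- suppressWarnings(drift_test(xi, times))
  expect_equal(rep$slope_per_hour, 1e3, tolerance = 1e-6)
  expect_lt(rep$p_value, 1e-6)
  expect_equal(rep$n_windows, 48)
  # matrix input: one row per gate
  rep2 <- suppressWarnings(drift_test(cbind(xi, rev(xi)), times))
  expect_equal(rep2$slope_per_hour, c(1e3, -1e3), tolerance = 1e-6)
  expect_error(drift_test(xi[1:50], times[1:50]), "2 full windows")
})

test_that("CoV and sample-size arithmetic reproduce closed forms", {
  cm <- cov_metrics(2, 40)
  expect_equal(cm$cov_percent, 5)
  expect_equal(cov_metrics(2, 40, n_avg = 16)$effective_cov_percent, 1.25)
  expect_equal(cov_metrics(0, 40, n_avg = 3)$effective_cov_percent, 0)
  expect_error(cov_metrics(2, 0), "positive")

  # margin = 1.96 sigma -> n = 1 (boundary)
  expect_equal(sample_size(1.7, qnorm(0.975) * 1.7), 1L)
  # halving the margin quadruples n before the ceiling
  n1 <- (qnorm(0.975) * 1.7 / 0.8)^2
  expect_equal(sample_size(1.7, 0.4), as.integer(ceiling(4 * n1)))
  expect_error(sample_size(1.7, -1), "positive")
  expect_error(sample_size(1.7, 0.5, confidence = 1.2), "confidence")
})

test_that("trial response recovers an injected deep-gate effect", {
  rate <- 10
  trial_len <- 33
  n_stim <- 6
  n_ctrl <- 6
  make_subject <- function(effect, seed) {
    set.seed(seed)
    dur <- 20 + (n_stim + n_ctrl) * trial_len + 40
    x <- 1 + 0.005 * as.numeric(
      stats::filter(rnorm(dur * rate, 0, 0.2), 0.98, method = "recursive")
    )
    onsets <- 20 + (seq_len(n_stim + n_ctrl) - 1) * trial_len
    stim <- sort(sample(seq_along(onsets), n_stim))
    t_axis <- seq_along(x) / rate
    for (i in stim) {
      # hyperaemic plateau spanning the whole response window
      resp <- effect * (t_axis >= onsets[i] + 5 & t_axis <= onsets[i] + 20)
      x <- x * (1 + resp)
    }
    list(rbfi = x, stim_onsets = onsets[stim],
         control_onsets = onsets[-stim])
  }
  cohort <- lapply(1:8, function(s) make_subject(0.10, seed = 100 + s))
  res <- trial_response(cohort, rate)
  expect_equal(res$mean, 10, tolerance = 0.05)  # percent units
  expect_lt(res$p_value, 0.05)

  null_cohort <- lapply(1:8, function(s) make_subject(0, seed = 200 + s))
  res0 <- trial_response(null_cohort, rate)
  expect_lt(abs(res0$mean), 1)

  # identical stim and control responses give exactly zero
  flat <- list(list(rbfi = rep(1, 2000), stim_onsets = c(30, 90),
                    control_onsets = c(60, 120)))
  expect_equal(trial_response(flat, rate)$per_subject, 0)

  # trials running past the end of the recording are dropped and counted
  short <- list(list(rbfi = rep(1, 500), stim_onsets = c(15, 32),
                     control_onsets = 20))
  res_s <- trial_response(short, rate)
  expect_equal(res_s$n_dropped, 1L)
  expect_equal(res_s$per_subject, 0)
})
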
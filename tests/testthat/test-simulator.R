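test_that("simulated streams are exactly reproducible from (config, seed)", {
  tm <- test_timing()
  med <- test_medium()
  irf <- test_irf()
  a <- simulate_gamma(med, tm, c(0.4, 1.0) * 1e-9, duration = 1,
                      n_channels = 2, irf = irf,
                      noise = noise_model(gamma_noise_sd = 0.05), seed = 99)
  b <- simulate_gamma(med, tm, c(0.4, 1.0) * 1e-9, duration = 1,
                      n_channels = 2, irf = irf,
                      noise = noise_model(gamma_noise_sd = 0.05), seed = 99)
  expect_identical(a$values, b$values)
  c <- simulate_gamma(med, tm, c(0.4, 1.0) * 1e-9, duration = 1,
                      n_channels = 2, irf = irf,
                      noise = noise_model(gamma_noise_sd = 0.05), seed = 100)
  expect_false(identical(a$values, c$values))
  expect_error(simulate_gamma(med, tm, 1e-9, duration = 1, n_channels = 1),
               "seed")
})

test_that("empirical autocorrelation follows exp(-xi tau) at lags 1-10", {
  tm <- test_timing()
  # static 10 kHz target at the single simulated gate
  med <- calibrate_medium(homogeneous_medium(), 10e3, 1e-9)
  gam <- simulate_gamma(med, tm, 1e-9, duration = 30, n_channels = 1,
                        seed = 21)
  z <- gam$values[, 1, 1]
  n <- length(z)
  lags <- 1:10
  ac <- Re(lag_autocorr(z, lags)) / mean(Mod(z)^2)
  truth <- exp(-10e3 * lags * tm$sweep_dt)
  # standard error of the normalized lag product: ~1/sqrt(n_indep), with
  # n_indep the number of decorrelation times in the stream
  se <- 1 / sqrt(30 * 10e3)
  expect_true(all(abs(ac - truth) < 3 * se))
})

test_that("mean |Gamma|^2 per gate tracks the IRF-convolved TPSF", {
  tm <- test_timing()
  med <- test_medium()
  irf <- test_irf()
  gates <- c(0.2, 0.4, 0.6, 0.8, 1.0) * 1e-9
  gam <- simulate_gamma(med, tm, gates, duration = 20, n_channels = 1,
                        irf = irf, seed = 31)
  p_hat <- apply(Mod(gam$values)^2, 2, mean)
  p_true <- gam$amplitude^2
  expect_equal(p_hat / p_hat[1], p_true / p_true[1], tolerance = 0.05)
})

test_that("interferogram synthesis round-trips through ifft_gamma", {
  tm <- sweep_timing(sweep_rate = 50e3, adc_rate = 50e3 * 128,
                     samples_per_sweep = 128)
  med <- test_medium()
  gates <- c(3, 9, 17) * tm$tof_spacing
  gam <- simulate_gamma(med, tm, gates, duration = 0.1, n_channels = 1,
                        seed = 5)
  frames <- simulate_interferograms(gam, tm, reference_amplitude = 2)
  rec <- ifft_gamma(frames)
  bins <- frames$bins + 1L
  ratio <- rec$values[, bins, 1] / gam$values[, , 1]
  # recovered Gamma equals the input up to one global complex scale (A/2)
  expect_lt(max(Mod(ratio - 1)), 1e-9)
  expect_equal(Mod(ratio[1, 1]), 1, tolerance = 1e-9)
  # scale is A_ref / 2 for interior bins of a real interferogram
  expect_equal(unique(round(Mod(rec$values[1, bins, 1] /
                                  gam$values[1, , 1]), 9)), 1)
})

test_that("zero field yields pure ADC noise; a static reflector peaks at its bin", {
  tm <- sweep_timing(sweep_rate = 50e3, adc_rate = 50e3 * 128,
                     samples_per_sweep = 128)
  gam0 <- make_gamma_series(matrix(0 + 0i, 2000, 1), tm, 5 * tm$tof_spacing)
  fr <- simulate_interferograms(gam0, tm, noise = noise_model(adc_noise_sd = 0.3),
                                seed = 8)
  expect_equal(sd(fr$samples), 0.3, tolerance = 0.02)
  expect_equal(mean(fr$samples), 0, tolerance = 0.01)

  # single static reflector at bin 11: processed TPSF peaks there
  b0 <- 11L
  gam1 <- make_gamma_series(matrix(1 + 0i, 500, 1), tm, b0 * tm$tof_spacing)
  fr1 <- simulate_interferograms(gam1, tm)
  tp <- average_tpsf(ifft_gamma(fr1), n_sweeps = 500)
  expect_equal(which.max(tp$magnitude[1, , 1]), b0 + 1L)
})

test_that("out-of-Nyquist gates are rejected", {
  tm <- sweep_timing(sweep_rate = 50e3, adc_rate = 50e3 * 64,
                     samples_per_sweep = 64)
  gam <- make_gamma_series(matrix(1 + 0i, 10, 1), tm, 40 * tm$tof_spacing)
  expect_error(simulate_interferograms(gam, tm), "Nyquist")
})

test_that("ratio normalization makes the scale factor drop out (round trip with taper off)", {
  # the round trip preserves relative gate amplitudes
  tm <- sweep_timing(sweep_rate = 50e3, adc_rate = 50e3 * 128,
                     samples_per_sweep = 128)
  z <- cbind(rep(2 + 1i, 50), rep(0.5 - 0.25i, 50))
  gam <- make_gamma_series(array(z, dim = c(50, 2, 1)), tm,
                           c(4, 12) * tm$tof_spacing)
  rec <- ifft_gamma(simulate_interferograms(gam, tm))
  r <- rec$values[1, c(5, 13), 1]
  expect_equal(r[2] / r[1], (0.5 - 0.25i) / (2 + 1i), tolerance = 1e-10)
})

test_that("pulsatility scales the decay rate between diastole and systole", {
  expect_error(pulsatility_model(diastolic_scale = 2, systolic_scale = 1))
  pm <- pulsatility_model(heart_rate = 1.2)
  w <- tofflow:::.cardiac_waveform(seq(0, 0.999, by = 0.001))
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(max(w), 1, tolerance = 1e-6)

  tm <- test_timing()
  med <- test_medium()
  gam <- simulate_gamma(med, tm, 1e-9, duration = 10, n_channels = 1,
                        pulsatility = pm, seed = 77)
  tr <- gam$truth
  expect_equal(tr$xi_dia, 28e3 * 15 / 28, tolerance = 1e-12)
  expect_equal(tr$xi_sys, 28e3 * 50 / 28, tolerance = 1e-12)
  expect_true(tr$xi_mean > tr$xi_dia && tr$xi_mean < tr$xi_sys)
  # beats arrive at the configured rate
  expect_equal(length(tr$beat_onsets), ceiling(10 * 1.2), tolerance = 1)
})
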
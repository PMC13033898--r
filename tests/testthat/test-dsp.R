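test_that("ifft_gamma matches the brute-force DFT oracle and is linear", {
  tm <- sweep_timing(sweep_rate = 50e3, adc_rate = 50e3 * 64,
                     samples_per_sweep = 64)
  set.seed(42)
  for (rep in 1:5) {
    y <- rnorm(64)
    g <- ifft_gamma(matrix(y, 1), timing = tm)
    oracle <- brute_ifft(y)
    expect_lt(max(Mod(g$values[1, , 1] - oracle)) / max(Mod(oracle)),
              1e-10)
  }
  # linearity
  a <- rnorm(64); b <- rnorm(64)
  ga <- ifft_gamma(matrix(a, 1), timing = tm)$values
  gb <- ifft_gamma(matrix(b, 1), timing = tm)$values
  gab <- ifft_gamma(matrix(2 * a - 3 * b, 1), timing = tm)$values
  expect_equal(gab, 2 * ga - 3 * gb, tolerance = 1e-12)
})

test_that("DC and cosine-fringe interferograms land in the expected bins", {
  tm <- sweep_timing(sweep_rate = 50e3, adc_rate = 50e3 * 64,
                     samples_per_sweep = 64)
  # constant frame: all energy in bin 0
  g <- ifft_gamma(matrix(3, 1, 64), timing = tm)
  mags <- Mod(g$values[1, , 1])
  expect_equal(mags[1], 3, tolerance = 1e-12)
  expect_lt(max(mags[-1]), 1e-12)
  # cosine fringe at integer frequency m: single peak at ToF bin m
  m_freq <- 9
  y <- cos(2 * pi * m_freq * (0:63) / 64)
  g <- ifft_gamma(matrix(y, 1), timing = tm)
  mags <- Mod(g$values[1, , 1])
  expect_equal(which.max(mags), m_freq + 1L)
  expect_equal(mags[m_freq + 1], 0.5, tolerance = 1e-12)
  expect_lt(max(mags[-(m_freq + 1)]), 1e-12)
  # all-zero frame passes through as all-zero Gamma
  g0 <- ifft_gamma(matrix(0, 2, 64), timing = tm)
  expect_true(all(Mod(g0$values) == 0))
})

test_that("TPSF averaging reduces to the frame magnitude for identical frames", {
  tm <- test_timing()
  z <- complex(real = rnorm(8), imaginary = rnorm(8))
  vals <- array(rep(z, each = 100), dim = c(100, 8, 1))
  gam <- make_gamma_series(vals[, , 1], tm, (0:7) * tm$tof_spacing)
  tp <- average_tpsf(gam, n_sweeps = 50)
  expect_equal(dim(tp$magnitude)[1], 2)  # two full blocks
  expect_equal(tp$magnitude[1, , 1], Mod(z), tolerance = 1e-12)
  expect_error(average_tpsf(gam, n_sweeps = 101), "partial")
})

test_that("TPSF bin variance shrinks like 1/n_sweeps for speckle frames", {
  tm <- test_timing()
  set.seed(7)
  n <- 20000
  z <- complex(real = rnorm(n), imaginary = rnorm(n)) / sqrt(2)
  gam <- make_gamma_series(matrix(z, ncol = 1), tm, 0)
  v_small <- var(average_tpsf(gam, n_sweeps = 100)$magnitude[, 1, 1])
  v_large <- var(average_tpsf(gam, n_sweeps = 1000)$magnitude[, 1, 1])
  expect_equal(v_small / v_large, 10, tolerance = 0.6)
})

test_that("zero-ToF location interpolates the IRF peak to sub-bin accuracy", {
  grid <- seq(0, 1e-9, by = 1e-11)
  # symmetric Gaussian centered exactly on a bin
  irf <- synth_irf(120e-12, grid, center = grid[41])
  expect_equal(locate_zero_tof(irf), grid[41], tolerance = 1e-15)
  # peak shifted 0.3 bins off-grid: recovered within 0.1 bin
  shift <- grid[41] + 0.3e-11
  irf_s <- structure(
    list(curve = exp(-(grid - shift)^2 / (2 * (50e-12)^2)),
         tof_axis = grid),
    class = "irf_record"
  )
  # dense-grid argmax of the same analytic curve as the oracle
  dense <- seq(0, 1e-9, by = 1e-14)
  oracle <- dense[which.max(exp(-(dense - shift)^2 / (2 * (50e-12)^2)))]
  est <- locate_zero_tof(irf_s)
  expect_lt(abs(est - shift), 0.1e-11)
  expect_lt(abs(est - oracle), 0.1e-11)
  # idempotence: after shifting the axis so the peak is zero, relocating
  # returns ~0
  irf_shifted <- irf_s
  irf_shifted$tof_axis <- grid - est
  expect_lt(abs(locate_zero_tof(irf_shifted)), 1e-13)
})

test_that("degenerate IRF peaks are rejected or flagged", {
  bad <- structure(list(curve = c(5, 4, 3, 2), tof_axis = (0:3) * 1e-11),
                   class = "irf_record")
  expect_error(locate_zero_tof(bad), "boundary")
  flat <- structure(list(curve = c(1, 2, 2, 1), tof_axis = (0:3) * 1e-11),
                    class = "irf_record")
  expect_warning(locate_zero_tof(flat), "earliest")
})

test_that("IRF width measurement matches geometry on a triangle", {
  w <- 100e-12
  grid <- seq(0, 1e-9, by = 1e-12)
  tri <- pmax(0, 1 - abs(grid - 0.5e-9) / w)
  irf <- structure(list(curve = tri, tof_axis = grid), class = "irf_record")
  expect_equal(irf_fwhm(irf), w, tolerance = 1e-9)
  # coarse 10 ps grid Gaussian: within half a bin of the fine-grid value
  coarse <- seq(0, 1e-9, by = 1e-11)
  g_c <- synth_irf(120e-12, coarse)
  g_f <- synth_irf(120e-12, seq(0, 1e-9, by = 1e-13))
  expect_lt(abs(irf_fwhm(g_c) - irf_fwhm(g_f)), 0.5e-11)
  # half level never crossed
  expect_error(
    irf_fwhm(structure(list(curve = c(0.9, 1, 0.9), tof_axis = (0:2) * 1e-11),
                       class = "irf_record")),
    "half"
  )
})

test_that("G1 of a constant stream is |A|^2 at every lag", {
  tm <- test_timing()
  a <- 2 - 1i
  gam <- make_gamma_series(matrix(a, 300, 1), tm, 0)
  g1 <- compute_g1(gam, 0, block = 64, stride = 32, max_lag = 10)
  expect_true(all(abs(Mod(g1$values) - Mod(a)^2) < 1e-12))
})

test_that("G1 record count and output rate follow the block arithmetic", {
  tm <- test_timing()
  set.seed(3)
  for (case in list(c(300, 64, 32), c(128, 128, 64), c(1000, 256, 128))) {
    n <- case[1]; block <- case[2]; stride <- case[3]
    z <- complex(real = rnorm(n), imaginary = rnorm(n))
    gam <- make_gamma_series(matrix(z, ncol = 1), tm, 0)
    g1 <- compute_g1(gam, 0, block = block, stride = stride, max_lag = 8)
    # enumeration oracle: count the valid block offsets directly
    n_oracle <- length(seq(0, n - block, by = stride))
    expect_equal(dim(g1$values)[1], n_oracle)
    expect_equal(n_oracle, floor((n - block) / stride) + 1)
    expect_equal(g1$output_rate, tm$sweep_rate / stride)
  }
  gam <- make_gamma_series(matrix(1 + 0i, 100, 1), tm, 0)
  expect_error(compute_g1(gam, 0, block = 64, stride = 32, max_lag = 64),
               "max_lag")
})

test_that("blocked G1 matches the direct lag-product estimator", {
  tm <- test_timing()
  set.seed(11)
  n <- 256
  z <- complex(real = rnorm(n), imaginary = rnorm(n))
  gam <- make_gamma_series(matrix(z, ncol = 1), tm, 0)
  g1 <- compute_g1(gam, 0, block = n, stride = n, max_lag = 6)
  oracle <- lag_autocorr(z, 0:6)
  expect_equal(g1$values[1, , 1], oracle, tolerance = 1e-12)
})
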
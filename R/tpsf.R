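#' Synthesize a Gaussian instrument response function
#'
#' Builds a unit-peak Gaussian IRF on a supplied ToF grid. The shape is a
#' modeling choice (only the width of a real instrument's IRF is typically
#' characterized); the default FWHM of 120 ps matches a swept-source system
#' with a ~13 GHz sweep.
#'
#' @param fwhm full width at half maximum, s (> grid spacing).
#' @param tof_grid uniformly spaced ToF axis, s.
#' @param center peak position, s; defaults to the middle grid point.
#' @return An object of class `irf_record` with fields `curve` (unit peak),
#'   `tof_axis`, `peak_tof`, and `fwhm`.
#' @export
synth_irf <- function(fwhm = 120e-12, tof_grid, center = NULL) {
  if (!is.numeric(fwhm) || fwhm <= 0) stop("fwhm must be positive")
  stopifnot(length(tof_grid) >= 3)
  dt <- diff(tof_grid)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1])) stop("tof_grid must be uniform")
  if (fwhm <= dt[1]) stop("fwhm must exceed the grid spacing")
  if (is.null(center)) center <- tof_grid[ceiling(length(tof_grid) / 2)]
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  curve <- exp(-(tof_grid - center)^2 / (2 * sigma^2))
  structure(
    list(curve = curve, tof_axis = tof_grid, peak_tof = center, fwhm = fwhm),
    class = "irf_record"
  )
}

#' Construct an IRF record from a measured curve
#'
#' @param curve IRF magnitude per ToF bin.
#' @param tof_axis uniformly spaced ToF axis, s.
#' @return An `irf_record`; `peak_tof` is the sub-bin peak location from
#'   [locate_zero_tof()] and `fwhm` from [irf_fwhm()].
#' @export
irf_record <- function(curve, tof_axis) {
  stopifnot(length(curve) == length(tof_axis), all(is.finite(curve)))
  rec <- structure(
    list(curve = curve, tof_axis = tof_axis, peak_tof = NA_real_,
         fwhm = NA_real_),
    class = "irf_record"
  )
  rec$peak_tof <- locate_zero_tof(rec)
  rec$fwhm <- irf_fwhm(rec)
  rec
}

# Convolve a density sampled on a uniform grid with an IRF kernel; the kernel
# is resampled onto the density's grid spacing when needed, aligned on its
# peak (the ToF zero convention) and normalized to unit sum so the density's
# mass is preserved.
.convolve_irf <- function(y, irf, spacing) {
  d_irf <- irf$tof_axis[2] - irf$tof_axis[1]
  if (abs(d_irf - spacing) <= 1e-6 * spacing) {
    kern <- irf$curve
  } else {
    grid <- seq(min(irf$tof_axis), max(irf$tof_axis), by = spacing)
    kern <- approx(irf$tof_axis, irf$curve, xout = grid)$y
  }
  kern <- kern / sum(kern)
  peak_idx <- which.max(kern)
  n <- length(y)
  full <- convolve(y, rev(kern), type = "open")  # length n + length(kern) - 1
  full[seq.int(peak_idx, peak_idx + n - 1)]
}

#' Diffusion-theory temporal point-spread function
#'
#' Time-resolved reflectance of a semi-infinite homogeneous turbid medium
#' (extrapolated point-source diffusion solution): the photon arrival-time
#' density at source-detector separation `sds`,
#' `R(t) ~ z0 (4 pi D v)^{-3/2} t^{-5/2} exp(-mu_a v t) exp(-(rho^2+z0^2)/(4 D v t))`,
#' with `D = 1/(3 mu_s')` and `z0 = 1/mu_s'`. The late tail decays with
#' log-slope approaching `-mu_a v`. For layered media the superficial layer's
#' optical properties are used; the TPSF here only sets the amplitude profile
#' of the simulated field, not its dynamics.
#'
#' @param medium a [medium_spec()].
#' @param tof_grid ToF axis, s (uniform, all >= 0).
#' @param sds source-detector separation, mm (default 10).
#' @param irf optional `irf_record` on a grid of the same spacing; if given,
#'   the IRF-convolved density is also returned.
#' @return A list with `raw` and (if `irf` supplied) `convolved` densities,
#'   each normalized to unit sum, plus `tof_axis` and a `coarse_grid` flag set
#'   when the grid cannot resolve the TPSF peak.
#' @export
tpsf_model <- function(medium, tof_grid, sds = 10, irf = NULL) {
  stopifnot(inherits(medium, "medium_spec"), length(tof_grid) >= 3)
  if (any(tof_grid < 0)) stop("tof_grid values must be nonnegative")
  lay <- medium$layers[[1]]
  v <- .light_speed(medium)
  D <- 1 / (3 * lay$mu_s_prime)        # cm
  z0 <- 1 / lay$mu_s_prime             # cm
  rho <- sds / 10                      # cm
  t <- tof_grid
  dens <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  dens[pos] <- z0 * (4 * pi * D * v)^-1.5 * tp^-2.5 *
    exp(-lay$mu_a * v * tp - (rho^2 + z0^2) / (4 * D * v * tp))
  if (!any(dens > 0)) stop("TPSF is identically zero on this grid")
  peak <- which.max(dens)
  # analytic peak time from d/dt log R = 0: mu_a v t^2 + (5/2) t = a
  a_c <- (rho^2 + z0^2) / (4 * D * v)
  t_peak <- (-2.5 + sqrt(6.25 + 4 * lay$mu_a * v * a_c)) /
    (2 * lay$mu_a * v)
  spacing <- tof_grid[2] - tof_grid[1]
  coarse <- peak == 1L || peak == length(dens) || spacing > t_peak
  if (coarse) {
    warning("tof_grid too coarse to resolve the TPSF peak")
  }
  raw <- dens / sum(dens)
  out <- list(raw = raw, tof_axis = tof_grid, coarse_grid = coarse)
  if (!is.null(irf)) {
    stopifnot(inherits(irf, "irf_record"))
    conv <- .convolve_irf(raw, irf, spacing = tof_grid[2] - tof_grid[1])
    out$convolved <- conv / sum(conv)
  }
  out
}
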
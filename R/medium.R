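#' A single optical layer of a dynamic turbid medium
#'
#' @param mu_a absorption coefficient, cm^-1 (> 0).
#' @param mu_s_prime reduced scattering coefficient, cm^-1 (> 0).
#' @param alpha_Db effective diffusion coefficient of the moving scatterers,
#'   cm^2/s (>= 0). The product `alpha_Db * mu_s_prime` is the flow-related
#'   quantity the decay rate is proportional to.
#' @param thickness layer thickness, mm (`Inf` allowed for a semi-infinite
#'   buffer layer).
#' @return An object of class `medium_layer`.
#' @export
medium_layer <- function(mu_a, mu_s_prime, alpha_Db, thickness = Inf) {
  stopifnot(
    is.numeric(mu_a), mu_a > 0,
    is.numeric(mu_s_prime), mu_s_prime > 0,
    is.numeric(alpha_Db), alpha_Db >= 0,
    is.numeric(thickness), thickness > 0
  )
  structure(
    list(mu_a = mu_a, mu_s_prime = mu_s_prime, alpha_Db = alpha_Db,
         thickness = thickness),
    class = "medium_layer"
  )
}

#' Logistic deep-path-fraction profile for layered media
#'
#' Returns a function f(ToF) giving the fraction of a detected photon's path
#' time spent in the deep layer. A smooth logistic is used: f is ~0 at early
#' ToF, rises around `onset` over a scale `scale`, and saturates at `f_max`.
#' The default onset of 0.4 ns matches the ToF at which a superficial layer of
#' around 12.5 mm stops dominating the detected signal.
#'
#' @param onset ToF at the half-rise point, s.
#' @param scale logistic width, s; the default 0.1 ns keeps the deep
#'   contribution below ~5% at 0.1 ns (photons that early cannot have
#'   crossed a ~12.5 mm superficial layer) while completing the crossover
#'   within a few hundred ps of the onset.
#' @param f_max asymptotic deep fraction in (0, 1].
#' @return A function mapping ToF (s) to a fraction in \[0, 1\].
#' @export
deep_fraction_logistic <- function(onset = 0.4e-9, scale = 0.1e-9,
                                   f_max = 1) {
  stopifnot(onset > 0, scale > 0, f_max > 0, f_max <= 1)
  function(tof) f_max / (1 + exp(-(tof - onset) / scale))
}

#' Specification of a 1- to 3-layer dynamic medium
#'
#' Layers are ordered superficial to deep; a third layer, when present, is a
#' static buffer and does not contribute dynamics. For layered media the
#' effective ToF-resolved dynamics are a `deep_fraction`-weighted mixture of
#' the superficial and deep `alpha_Db * mu_s_prime` products.
#'
#' @param layers a list of [medium_layer()] objects (1 to 3, superficial
#'   first).
#' @param refractive_index medium refractive index (>= 1).
#' @param wavelength source wavelength, nm.
#' @param deep_fraction function mapping ToF (s) to the fraction of photon
#'   path time in the deep layer; required only for multi-layer media.
#'   Defaults to [deep_fraction_logistic()].
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(layers, refractive_index = 1.33, wavelength = 1064,
                        deep_fraction = NULL) {
  if (inherits(layers, "medium_layer")) layers <- list(layers)
  stopifnot(
    is.list(layers), length(layers) >= 1, length(layers) <= 3,
    all(vapply(layers, inherits, logical(1), "medium_layer")),
    refractive_index >= 1, wavelength > 0
  )
  if (length(layers) >= 2 && is.null(deep_fraction)) {
    deep_fraction <- deep_fraction_logistic()
  }
  if (!is.null(deep_fraction)) stopifnot(is.function(deep_fraction))
  structure(
    list(layers = layers, refractive_index = refractive_index,
         wavelength = wavelength, deep_fraction = deep_fraction),
    class = "medium_spec"
  )
}

#' Convenience constructor for a homogeneous medium
#'
#' @inheritParams medium_layer
#' @inheritParams medium_spec
#' @return A `medium_spec` with a single layer.
#' @export
homogeneous_medium <- function(mu_a = 0.12, mu_s_prime = 7.4,
                               alpha_Db = 1e-8, refractive_index = 1.33,
                               wavelength = 1064) {
  medium_spec(list(medium_layer(mu_a, mu_s_prime, alpha_Db)),
              refractive_index = refractive_index, wavelength = wavelength)
}

# In-medium wavenumber, cm^-1: 2*pi*n / lambda0. Using the in-medium value is
# a convention of this package; the DWS decay law is derived in the medium.
.wavenumber <- function(medium) {
  2 * pi * medium$refractive_index / (medium$wavelength * 1e-7)
}

# Speed of light in the medium, cm/s.
.light_speed <- function(medium) .C_CM_S / medium$refractive_index

#' DWS decay rate versus photon time of flight
#'
#' Evaluates the diffusing-wave-spectroscopy prediction for the decay rate of
#' the time-of-flight-resolved field autocorrelation,
#' `xi(ToF) = 2 k^2 alpha_Db mu_s' v ToF`, where `k` is the in-medium optical
#' wavenumber and `v` the speed of light in the medium. For layered media the
#' `alpha_Db * mu_s'` product is the deep-fraction-weighted mixture of the
#' superficial and deep layers.
#'
#' @param medium a [medium_spec()].
#' @param tof_grid photon times of flight, s (all >= 0, nonempty).
#' @return Decay rates in Hz, one per ToF value.
#' @export
decay_rate_profile <- function(medium, tof_grid) {
  stopifnot(inherits(medium, "medium_spec"))
  if (length(tof_grid) == 0) stop("tof_grid must be nonempty")
  if (any(!is.finite(tof_grid)) || any(tof_grid < 0)) {
    stop("tof_grid values must be finite and nonnegative")
  }
  k <- .wavenumber(medium)
  v <- .light_speed(medium)
  prods <- vapply(medium$layers, function(l) l$alpha_Db * l$mu_s_prime,
                  numeric(1))
  if (length(medium$layers) == 1) {
    prod_eff <- prods[1]
  } else {
    f <- medium$deep_fraction(tof_grid)
    if (any(f < 0 | f > 1)) stop("deep_fraction must lie in [0, 1]")
    if (is.unsorted(f)) stop("deep_fraction must be nondecreasing in ToF")
    prod_eff <- (1 - f) * prods[1] + f * prods[2]
  }
  2 * k^2 * v * tof_grid * prod_eff
}

#' Calibrate a medium's dynamics to a target decay rate
#'
#' Uniformly rescales every layer's `alpha_Db` so the medium's decay rate at a
#' reference ToF equals a target value (e.g. the 28 kHz population-mean decay
#' rate at 1 ns). Leaves the ToF dependence and layer contrast unchanged.
#'
#' @param medium a [medium_spec()].
#' @param xi_target target decay rate at `tof_ref`, Hz (> 0).
#' @param tof_ref reference ToF, s (default 1 ns).
#' @return The rescaled `medium_spec`.
#' @export
calibrate_medium <- function(medium, xi_target, tof_ref = 1e-9) {
  stopifnot(xi_target > 0, tof_ref > 0)
  xi_now <- decay_rate_profile(medium, tof_ref)
  if (xi_now <= 0) stop("medium has no dynamics at the reference ToF")
  scale <- xi_target / xi_now
  medium$layers <- lapply(medium$layers, function(l) {
    l$alpha_Db <- l$alpha_Db * scale
    l
  })
  medium
}
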
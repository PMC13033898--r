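#' Swept-source acquisition timing
#'
#' Describes one laser sweep: the sweep repetition rate (which sets the
#' autocorrelation lag unit, one sweep period), the optical sweep bandwidth
#' (which sets the time-of-flight bin spacing after the inverse FFT), and the
#' digitizer rate. The full-rate defaults correspond to a 200 kHz sawtooth
#' sweep spanning 13.2 GHz digitized at 100 MHz, i.e. 500 samples per sweep,
#' a 5 microsecond lag unit and a 75.8 ps ToF bin.
#'
#' @param sweep_rate sweep repetition rate, Hz.
#' @param sweep_bandwidth optical sweep bandwidth, Hz.
#' @param adc_rate digitizer sampling rate, Hz. Must be an integer multiple of
#'   `sweep_rate`.
#' @param samples_per_sweep number of digitized samples per sweep; defaults to
#'   `adc_rate / sweep_rate`.
#' @param tof_spacing time-of-flight bin spacing, s. Defaults to
#'   `1 / sweep_bandwidth`; configurable because the effective (apodized)
#'   bandwidth of a real instrument can differ from the nominal sweep span.
#' @return An object of class `sweep_timing`.
#' @export
sweep_timing <- function(sweep_rate = 200e3, sweep_bandwidth = 13.2e9,
                         adc_rate = 100e6, samples_per_sweep = NULL,
                         tof_spacing = NULL) {
  stopifnot(sweep_rate > 0, sweep_bandwidth > 0, adc_rate > 0)
  if (is.null(samples_per_sweep)) {
    samples_per_sweep <- adc_rate / sweep_rate
  }
  if (abs(samples_per_sweep - round(samples_per_sweep)) > 1e-8) {
    stop("samples_per_sweep = adc_rate / sweep_rate must be an integer")
  }
  samples_per_sweep <- as.integer(round(samples_per_sweep))
  if (is.null(tof_spacing)) tof_spacing <- 1 / sweep_bandwidth
  structure(
    list(
      sweep_rate = sweep_rate,
      sweep_bandwidth = sweep_bandwidth,
      adc_rate = adc_rate,
      samples_per_sweep = samples_per_sweep,
      sweep_dt = 1 / sweep_rate,
      tof_spacing = tof_spacing
    ),
    class = "sweep_timing"
  )
}

#' Desk-scale acquisition timing
#'
#' A decimated timing preset intended for simulation studies on a single CPU:
#' the sweep rate is reduced 4-fold to 50 kHz (lag unit 20 microseconds) and
#' the per-sweep sample count to 512, while the ToF bin spacing is kept at the
#' full-rate value. The 4-fold decimation is the largest that keeps the
#' in vivo range of g1 decay rates (roughly 5--50 kHz) resolvable within the
#' first few autocorrelation lags; block and stride are shrunk by the same
#' factor elsewhere so the ~48.8 Hz decay-rate output rate is preserved.
#'
#' @return A `sweep_timing` object.
#' @export
desk_timing <- function() {
  sweep_timing(
    sweep_rate = 50e3, sweep_bandwidth = 13.2e9,
    adc_rate = 50e3 * 512, samples_per_sweep = 512
  )
}
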
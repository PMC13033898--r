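# tofflow

Processing and simulation toolkit for **time-of-flight-resolved
interferometric blood-flow measurements** (interferometric NIRS / time-domain
diffuse correlation). It is written for researchers working with swept-source
interferometric systems that record, per laser sweep, a wavenumber-domain
interferogram whose inverse Fourier transform yields the complex, ToF-resolved
optical field — the mutual coherence function Γ(ToF) — and who want to turn
those streams into pulsatile, depth-resolved blood-flow indices with
quantified signal quality.

## The model

Light that spends longer in tissue (later photon time of flight, ToF) samples
deeper layers on average. Diffusing-wave spectroscopy predicts that the
ToF-resolved electric-field autocorrelation decays as a single exponential,

```
g1(tau, ToF) = exp(-xi(ToF) * tau),     xi(ToF) = 2 k^2 (alpha Db) mu_s' v ToF
```

where `k` is the in-medium optical wavenumber, `alpha Db` the effective
diffusion coefficient of the moving scatterers (red blood cells), `mu_s'` the
reduced scattering coefficient and `v` the speed of light in the medium. The
decay rate `xi` is linear in ToF and proportional to the flow-related product
`alpha Db * mu_s'`; its time course at a late ToF gate (≥ 1 ns) tracks
cerebral blood flow with high brain specificity. The pipeline implemented
here is

1. **iFFT** of each sweep's interferogram → Γ(ToF) per channel
   (`ifft_gamma`), with TPSF formation by magnitude averaging
   (`average_tpsf`) and the ToF origin anchored at the instrument response
   function peak (`locate_zero_tof`);
2. **blocked autocorrelation** of Γ at each ToF gate (block 8192, stride
   4096 at the 200 kHz sweep rate → ~48.8 Hz output) (`compute_g1`);
3. **multiset-CCA denoising** across detection channels, per gate
   (`mcca_fit` / `mcca_apply`);
4. **normalization** at the first lag, **channel combination**, and an
   anchored single-exponential **fit** of |g1| with the
   `g1 > 0.5 & tau < 100 us`-or-first-five-lags truncation rule
   (`normalize_g1`, `combine_channels`, `fit_decay_series`);
5. **rBFi** formation against a baseline window (`rbfi`), low-pass filtering
   (`lowpass_rbfi`), pulse segmentation and the **pulse variance ratio**
   quality statistic with its corner-ToF summary (`segment_pulses`, `pvr`,
   `corner_tof`), plus depth-sensitivity, drift, CoV and functional-response
   statistics (`sliding_gradient`, `sensitivity_onset`, `drift_test`,
   `cov_metrics`, `trial_response`).

A physics-based simulator (`simulate_gamma`, `simulate_interferograms`)
generates Γ streams as complex Ornstein–Uhlenbeck speckle whose
autocorrelation follows the decay law exactly, with amplitudes shaped by a
diffusion-theory TPSF convolved with the IRF, shared cardiac pulsatility
across channels, and full ground truth — so every processing stage is
testable without hardware.

## Worked example

Simulate a homogeneous tissue-like medium (mu_a = 0.12 cm^-1, mu_s' =
7.4 cm^-1) calibrated to a 28 kHz decay rate at 1 ns, run the full pipeline
at the desk-scale preset (50 kHz decimated sweep rate, 60 s, 4 channels, six
gates from 0.2 to 1.2 ns), and compare fitted decay rates with the decay-law
prediction:

```r
library(tofflow)
res <- run_pipeline(desk_preset(seed = 1))
data.frame(tof_ns = res$summary$tof_ns,
           fit_khz = round(res$summary$xi_mean_khz, 2),
           truth_khz = res$summary$xi_truth_khz)
#>   tof_ns fit_khz truth_khz
#> 1    0.2    5.61       5.6
#> 2    0.4   11.15      11.2
#> 3    0.6   16.84      16.8
#> 4    0.8   22.48      22.4
#> 5    1.0   27.78      28.0
#> 6    1.2   33.57      33.6
round(res$summary$slope_error_pct, 2)
#> [1] -0.17
```

The fitted ξ-vs-ToF line passes through the origin with a slope within half a
percent of `2 k^2 (alpha Db) mu_s' v` — the end-to-end parameter-recovery
check. `res$rbfi` holds the relative blood-flow index per gate;
`run_pipeline(..., output_dir = "out")` additionally writes `xi_vs_tof.csv`,
`summary.csv` and a plain-text session container.

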
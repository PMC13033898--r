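---
title: "Methods: time-of-flight-resolved interferometric blood-flow processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-of-flight-resolved interferometric blood-flow processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tofflow)
```

## The measurement and its model

A swept-source interferometric flow monitor sweeps a long-coherence laser
across a bandwidth $B$ at a repetition rate $f_s$ and interferes the light
returning from tissue with a reference arm. Each sweep's digitized
interferogram is, up to noise, a superposition of fringes whose frequencies
encode photon time of flight (ToF); an inverse discrete Fourier transform
recovers the complex mutual coherence function $\Gamma(\mathrm{ToF})$ — the
ToF-resolved optical field — once per sweep. Magnitude averaging over many
sweeps yields the temporal point-spread function (TPSF); the sweep-to-sweep
evolution of $\Gamma$ at a fixed ToF carries the speckle dynamics of moving
scatterers.

Diffusing-wave spectroscopy gives the working model: at a given ToF the
normalized field autocorrelation decays as a single exponential,
$g_1(\tau) = e^{-\xi\,\tau}$ with

$$\xi(\mathrm{ToF}) = 2 k^2\, \alpha D_b\, \mu_s'\, v\, \mathrm{ToF},$$

where $k = 2\pi n/\lambda_0$ is the in-medium wavenumber (a convention of
this package; $n = 1.33$ by default), $v = c/n$, $\mu_s'$ the reduced
scattering coefficient, and $\alpha D_b$ the effective diffusion coefficient
of the moving scatterers. Only the product $\alpha D_b\,\mu_s'$ is
identifiable from the decay rate; the package never attempts to separate the
two factors. For layered media the package models the effective product as a
mixture $(1-f)\,p_{\rm sup} + f\,p_{\rm deep}$, with $f(\mathrm{ToF})$ a
nondecreasing deep-path-time fraction.

## Assumptions

* **Single-exponential decay per gate.** Real layered tissue produces a
  mixture of decorrelation rates within one gate; the fitted $\xi$ is then an
  effective motion parameter. This is the same approximation the method
  itself makes, and the simulator adopts it as its generative model.
* **A ToF gate is one IRF-wide window.** Gates are represented by the single
  ToF bin at the gate center; the instrument response function (IRF), whose
  FWHM (default 120 ps) exceeds the bin spacing ($1/B \approx 75.8$ ps at
  13.2 GHz), makes each bin an effectively IRF-wide window. The IRF peak
  defines ToF $= 0$.
* **Phase-stable normalization.** Fitting uses $|g_1|$ (a config switch
  allows the real part), which is robust to slow phase drift at the cost of
  a small noise-rectification bias at low SNR (quantified below).

## Pipeline parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| sweep rate $f_s$ | 200 kHz (full) / 50 kHz (desk) | Hz | lag unit $\Delta t = 1/f_s$ |
| sweep bandwidth $B$ | 13.2 GHz | Hz | ToF bin spacing $1/B$ (configurable, since the effective bandwidth of a real instrument may be narrower than the sweep span) |
| TPSF average | 40,960 sweeps | – | ~0.2 s, ~5 Hz TPSF rate at full rate |
| G1 block / stride | 8192 / 4096 (full), 2048 / 1024 (desk) | sweeps | output rate $f_s/\mathrm{stride} \approx 48.8$ Hz in both presets |
| max lag | 20 | lags | fit-window ceiling ($100\,\mu s$ at full rate) |
| $\tau_1$ | $\Delta t$ | s | normalization lag; $g_1(\tau_1) = 1$ |
| truncation rule | $|g_1|>0.5,\ \tau<100\,\mu s$, else first 5 lags | – | the ceiling scales with $\Delta t$ in the desk preset |
| mCCA calibration / keep | 500 samples / 4 components | – | ~10 s at the ~50 Hz output |
| PVR pulses / threshold | 10 / 0.6 | – | corner-ToF quality rule |
| gradient window / z | 5 points / $|z| > 10$ | – | depth-sensitivity onset |
| drift window | 30 min | – | nonoverlapping means, slope t-test |

## The synthetic-data generator

`simulate_gamma` draws, per (channel, gate), a complex first-order
autoregressive (discrete Ornstein–Uhlenbeck) stream
$\Gamma_{n+1} = \rho_n \Gamma_n + \sqrt{1-\rho_n^2}\,\varepsilon_n$ with
$\rho_n = e^{-\xi(\mathrm{ToF},t_n)\Delta t}$ and circular complex Gaussian
innovations. This is the minimal process whose autocorrelation is exactly
$e^{-\xi\tau}$ at every lag, which is what makes parameter recovery an exact
oracle; it deliberately omits higher-order path physics (Monte Carlo photon
transport, sweep nonlinearity, polarization). Gate amplitudes follow
$\sqrt{\mathrm{TPSF} \ast \mathrm{IRF}}$, with the TPSF from the
semi-infinite diffusion-theory time-resolved reflectance
(extrapolated-source form, $D = 1/3\mu_s'$, $z_0 = 1/\mu_s'$) at the 10 mm
source–detector separation, so mean $|\Gamma|^2$ traces the measured photon
arrival-time density. Cardiac pulsatility scales $\xi$ between diastolic and
systolic values along a shared waveform (sinusoidal upstroke over 15% of the
beat, exponential decay with a quarter-beat time constant); the default
diastolic/systolic scales 15/28 and 50/28 reproduce, for a medium calibrated
to 28 kHz at 1 ns, the in vivo median 15–50 kHz range at that ToF. One root
seed derives deterministic child streams per (channel, gate), so every run
is exactly reproducible.

**What the generator does not emulate:** motion artifacts, channel-dependent
coupling drift, sweep-to-sweep phase noise, detector nonlinearity, and the
layered-path statistics of real heads. Passing tests therefore demonstrate
the correctness and calibration of the *processing*, not the device physics
of any particular instrument.

**Noise calibration.** The additive complex field noise of the desk preset
(`gamma_noise_sd = 0.05` relative to the unit peak amplitude) is set so that
the static homogeneous session's fitted decay-rate noise at 1 ns and the
~50 Hz output is $\approx 1.6$ kHz — matching the ~1.7 kHz stability a
well-engineered instrument of this class achieves; the speckle-only floor of
the preset is ~1.2 kHz.

## Desk-scale preset

Tests and examples run a 4-fold decimated preset: 50 kHz sweep rate, 512
samples per sweep, block 2048 / stride 1024 (preserving the ~48.8 Hz output
rate), 60 s of data, 4 channels, six gates from 0.2 to 1.2 ns. Decimating
much further (say to 2 kHz) would make a 28 kHz decay rate decorrelate
completely within a single lag ($e^{-14}$), leaving nothing to fit; 4-fold
is the largest decimation that keeps the in vivo decay-rate range resolvable
in the first few lags while cutting simulation cost by 4. The lag-time fit
ceiling scales with the lag unit (20 lags in both presets).

## Numerical choices

* **Autocorrelation estimator**: unbiased per-lag pair counts
  ($\sum \bar\Gamma_n \Gamma_{n+j} / (N_{\rm block}-j)$); with max lag 20 of
  a 2048–8192 block the bias distinction is negligible, and the unbiased
  form makes the flat-stream invariant exact.
* **Decay fit**: `stats::nls` (`port`, $\xi \ge 0$) of
  $|g_1| \sim e^{-\xi(\tau-\tau_1)}$, anchored at the normalization point,
  initialized from the through-origin log-linear slope, unweighted (at most
  20 points; robustness is preferred over optimal weighting). Negative fits
  are clipped to zero and flagged. At low per-record SNR the magnitude
  rectifies noise and biases single-record fits slightly low (about
  $-1$% at the 1 ns desk-preset gate); channel combination averages
  $|g_1|$ across channels, which reduces variance but not this bias —
  denoising does, which is why raw-vs-denoised comparisons show a small
  mean shift well inside the Bland–Altman limits of agreement.
* **mCCA**: MAXVAR formulation — the generalized eigenproblem
  $R w = \lambda D w$ with $R$ the covariance of the channel-concatenated
  data (real and imaginary lag parts stacked, keeping the problem
  real-symmetric) and $D$ its channel-block-diagonal part, ridge-regularized
  by $10^{-6}\times$ the mean diagonal. Eigenvalues rank cross-channel
  consistency (a perfectly shared component attains the channel count).
  Back-projection weights come from an SVD-pseudoinverse least-squares fit
  on the calibration block, which handles rank-deficient calibration data;
  keeping all components reproduces the input exactly. Calibration happens
  once per session (500 records); each gate is fitted independently so no
  information mixes across ToF.
* **Zero-phase filters**: Butterworth via forward–backward filtering with
  mean removal and reflected end padding, so constants pass exactly and edge
  transients stay out of the series. The 0.5 Hz low-pass (order 4, applied
  twice) attenuates a 1.2 Hz cardiac line by more than 20 dB.
* **Beat detection**: troughs of the 0.5–5 Hz band-passed series with a
  0.3 s refractory period, each refined to the raw-signal minimum within
  ±0.15 s (the band-pass shifts minima of asymmetric waveforms slightly
  early).
* **Sub-bin peak location**: three-point parabolic interpolation around the
  discrete IRF maximum; boundary peaks error, ties take the earliest with a
  warning.

## Design decisions where the design was open

* **PVR orientation.** The pulse variance ratio is
  $1 - \langle\sigma^2_{\rm across}\rangle / \langle\sigma^2_{\rm within}\rangle$:
  with per-pulse z-scoring the within-pulse variance is 1 by construction,
  the across-pulse variance at each time sample vanishes for identical
  pulses (PVR $=1$), approaches 1 for i.i.d. noise (PVR $\approx 0$; its
  exact finite-sample expectation is $+1/N_{\rm samples}$), and can exceed 1
  for anti-correlated noise (PVR $<0$). Only this orientation yields those
  anchor values.
* **Corner ToF on non-monotone profiles**: the literal maximum qualifying
  gate is the default; a contiguous-prefix variant is available by flag.
* **Pulse-train choice within a recording**: rolling 10-pulse windows with
  the median PVR reported, rather than privileging any single train.
* **Gradient z-test**: $z = (b_1-b_2)/\sqrt{SE_1^2+SE_2^2}$ with
  residual-based OLS slope standard errors. A consequence worth knowing:
  a window straddling a sharp gradient kink carries the kink's misfit in its
  own SE, so the earliest window that registers as *measurably* different is
  the first one lying wholly on the changed segment — its last point, one
  window span past the change, is the reported onset. No multiple-testing
  correction is applied across gates or windows, matching per-gate
  reporting conventions.
* **Channel combination** averages $|g_1|$ per lag over valid channels
  (after normalization, before fitting); fitted-rate averaging is the main
  alternative and gives close results at these SNRs.
* **Sample-size margin**: the normal-approximation formula
  $n = \lceil (z_{(1+c)/2}\,\sigma/m)^2 \rceil$ exposes the precision margin
  $m$ as a parameter (with $\sigma = 1.7$ kHz, a 0.75 kHz margin at 95%
  confidence gives $n = 20$).
* **Session container**: a directory of JSON metadata and full-precision
  (`%.17g`) CSV arrays mirroring the group layout
  `/meta, /raw, /gamma, /irf, /tpsf, /g1/<gate>, /xi, /rbfi, /truth`. Being
  plain text, sessions are diffable and round-trip bit-identically; units
  and axes ride along in the per-group metadata, and any stochastic content
  requires the seed in `/meta`.

## Problem sizes used by the tests

The test suite and acceptance script run entirely at the desk scale: the
parameter-recovery run simulates 60 s × 4 channels × 6 gates (3 × 10⁶ sweeps
per stream), the noise and bias-check sessions 40 s at one gate, drift
calibration uses 1000 replicates of a 24 h series sampled per minute, and
the PVR Monte Carlo 2000 draws of 10 × 100 matrices. Full-rate settings
(200 kHz, block 8192) remain available through `run_config(timing = "full")`
and are used for the arithmetic-level tests where no simulation is needed.

## Known limitations

* The decay rate conflates $\alpha D_b$ and $\mu_s'$; no absolute flow
  calibration is attempted.
* The AR(1) speckle model has no intrinsic $\beta$-like coherence factor and
  no multi-rate mixtures within a gate; real multilayer media produce
  gate-level rate mixtures the single-exponential fit summarizes.
* mCCA assumes the shared-across-channels subspace is signal; a globally
  coherent artifact (e.g. motion) would be retained, not rejected.
* The depth-sensitivity onset depends on the window width and the SE
  convention documented above; with residual-based SEs it is reported one
  window span after a sharp change.
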
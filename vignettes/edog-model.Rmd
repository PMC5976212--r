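---
title: "The eDOG model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The eDOG model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edogsim)
```

## The model

Relay cells of the dorsal lateral geniculate nucleus (dLGN) sit between
retina and visual cortex, and receive — besides their retinal drive — massive
feedback from cortical layer 6.  The extended difference-of-Gaussians (eDOG)
model treats every cell population as a two-dimensional sheet of identical
firing-rate units coupled by spatially homogeneous kernels.  Under linearity
the response of a neuron at retinotopic position $\mathbf r$ to a stimulus
$S$ is a convolution $R = W * S$ with an impulse-response function
$W(\mathbf r, t)$, i.e. a product in Fourier space,
$\tilde R = \tilde W \tilde S$.

The circuit contains four kinds of coupling:

* the retinal input $W_G = F(\mathbf r)\,H(t)$, a difference-of-Gaussians
  (DOG) spatial profile times a biphasic time course;
* direct feedforward excitation $K_{RG}$ from retinal ganglion cells;
* indirect feedforward inhibition $K_{RIG}$ via intrageniculate
  interneurons;
* thalamo-cortico-thalamic feedback loops $K_{RCR}$ (relay → cortex →
  relay), which may be excitatory, inhibitory, or a mix of a narrow
  excitatory and a broad inhibitory arm.

Cortical cells are half-wave rectified, but because every ON–ON feedback
connection is accompanied by a phase-reversed OFF–ON connection the
rectification cancels algebraically ($H[x] - H[-x] = x$) and the relay-cell
transfer function is closed-form:

$$\tilde W_R(\mathbf k, \omega) \;=\;
  \frac{w_{RG}\tilde f_{RG}\tilde h_{RG}
      + w_{RIG}\tilde f_{RIG}\tilde h_{RIG}}
       {1 - \sum_j w_j \tilde f_j \tilde h_j}\;
  \tilde F(k)\,\tilde H(\omega).$$

All coupling kernels are separable, $K = w\,f(r)\,h(t)$, with normalized
parts: $f$ a unit-mass Gaussian of width $a$ (degrees), $h$ a delayed
exponential with delay $\Delta$ and time constant $\tau$ (ms).  The model is
developed for the ON pathway; an OFF-pathway twin differs only by sign
conventions and is not implemented.  Orientation-selective cortical
populations enter only through their sum over all orientations, which is
essentially circularly symmetric; the package therefore supports circularly
symmetric kernels only.

## Parameters

`edog_circuit_table1()` builds the stock cat parameterization:

| connection | weight | spatial width (deg) | temporal |
|---|---|---|---|
| retinal DOG | 1 (fixed) | center 0.62, surround 1.26 (A = 1, B = 0.85) | biphasic, 42.5 ms phases, rebound weight 0.38 |
| feedforward excitation | +1 | 0.1 | $\Delta$ = 0, $\tau$ = 5 ms |
| feedforward inhibition | −0.5 | 0.3 | $\Delta$ = 3, $\tau$ = 5 ms |
| excitatory feedback | +0.5 | 0.83 | $\Delta$ ∈ 5–30 ms, $\tau$ = 5 ms |
| inhibitory feedback | −0.5 | 0.83 | $\Delta$ ∈ 5–30 ms, $\tau$ = 5 ms |
| mixed feedback | +0.3 / −0.6 | 0.1 / 0.9 | as above |

Loop delays default to a fast excitatory (5 ms) and slow inhibitory (30 ms)
feedback, the configuration that best reproduces feedback phenomenology
(enhanced centre–surround antagonism, sharper temporal tuning, temporal
decorrelation); `delta_ex` and `delta_in` expose them.  Feedback weights
scale jointly through `feedback_factor`, matching how feedback strength is
swept in physiological comparisons.

Firing-rate units are arbitrary: the model fixes no absolute rate scale, so
every shipped measure is a ratio, a percentage, or an argmax location.

## Fourier conventions and discretization

The package-wide convention is
$\tilde W(\mathbf k,\omega) = \iint W\, e^{-i(\mathbf k\cdot\mathbf r
- \omega t)}\, d^2r\, dt$, chosen so that a drifting plane wave
$\cos(\mathbf k_g\cdot\mathbf r - \omega_g t)$ probes $\tilde W$ exactly at
$(\mathbf k_g, \omega_g)$.  All closed-form transforms (Gaussian, DOG,
delayed exponential, biphasic) were derived under this convention and are
verified against dense discrete-Fourier and quadrature oracles in the test
suite; the biphasic transform has removable singularities at
$\omega = \pm\pi/\tau$ that are evaluated by their analytic limits.

`stgrid()` owns the discretization: `nx` pixels per spatial axis over
`extent` degrees (centered axes, analyzed neuron at index `nx/2 + 1`) and
`nt` steps over `duration` ms.  The default grid is 128 px over 10 deg
(dx ≈ 0.078 deg) and 512 steps over 1000 ms (dt ≈ 1.95 ms): it covers the
DOG surround and the longest loop delays with ample margin, and resolves
the narrowest stock kernel (0.1 deg) marginally — 256 px (or a smaller
extent) is recommended when fine spatial structure of that kernel matters.
A warning fires when `dx` exceeds the narrowest kernel width outright, and
when any kernel's width exceeds a quarter of the extent (periodic
wrap-around risk).

Numerical details worth knowing:

* **Hermitian symmetrization.**  Sampling the continuous transfer function
  on a DFT grid leaves the unpaired Nyquist bins slightly asymmetric; the
  sampled field is projected onto exact Hermitian symmetry before inversion
  so real-space fields are real to rounding error.
* **Causality / leakage check.**  Inverse transforms are interpreted on
  $t \in [0,$ `duration`$)$.  The late-time magnitude is required to stay
  below $10^{-3}$ of the peak, else a warning suggests enlarging
  `duration`.  The floor is set by spectral truncation of the biphasic
  kernel (its transform decays only algebraically in $\omega$), typically
  $\sim 10^{-4}$ of the peak on the default grid, so a much tighter bound
  would flag every run without indicating genuine wrap-around.
* **Instability policy.**  The feedback loop gain denominator
  $1 - \sum w\tilde f\tilde h$ is checked wherever the transfer function is
  evaluated: magnitudes below $10^{-6}$ raise an error naming the offending
  frequency, between $10^{-6}$ and $0.05$ a warning.  The model itself is
  silent on what a vanishing denominator means physically;
  `stability_check()` scans a grid and reports the minimum.
* **Grating snapping.**  Full-field gratings must live exactly on DFT bins
  and are snapped by `align_wavevector()` (ties toward lower magnitude).
  Patch gratings are windowed by a finite disc and are therefore built in
  real space at the requested wavenumber without snapping — a 0.25 rad/deg
  probe is representable even when the bin spacing is coarser.
* **Static path.**  Static stimuli factorize as
  $\tilde W_R(k, 0) = \tilde W_R^{sp}(k)\,\tilde H(0)$ with all
  $\tilde h(0) = 1$.  The constant $\tilde H(0) = (2\tau/\pi)(1-B)$ is kept
  explicitly, so static and dynamic paths agree numerically at
  $\omega = 0$.  Slowly drifting patch gratings (a few Hz, as in area
  summation experiments) are evaluated in the fast-loop limit through the
  same static path, taking the value at cosine phase zero at the patch
  center; the patch is always concentric with the analyzed neuron.
* **Disc masks.**  A pixel belongs to a spot iff its center lies within the
  radius — deterministic, no anti-aliasing, matching the sharp Heaviside
  edge of the stimulus definition.

## Measures

* `rf_characteristics()`: center excitation and surround inhibition are the
  field extrema; receptive-field size is the first sign change of the
  radial profile along +x, linearly interpolated between the bracketing
  samples.
* `area_response_curve()` / `suppression_index()`: $R_\mathrm{plateau}$ is
  the mean response over the largest 10% of diameters, with a "plateau not
  reached" warning when it varies by more than 1% there; when the curve
  maximum falls inside that window the curve never descends to a distinct
  plateau and the index is 0 by construction.
* `optimal_size()` and all peak latencies refine the argmax by three-point
  quadratic interpolation; ties break toward the smaller argument.
* `temporal_irf_measures()`: the rebound of a multiphasic trace is the
  global minimum after the first positive peak, not the first local
  minimum — with strongly delayed inhibition, later lobes can be deeper and
  the global choice is what the biphasic index is meant to capture.
* `response_reduction()` uses the 1.5 deg / 10 deg diameter pair (center
  only vs center plus surround) by default.
* Flashing-spot area-response curves summarize the center trace by its
  peak absolute value by default (`summary = "peak"`); the transient/
  sustained split is exposed through `"mean"` and `"sustained"` since no
  single canonical scalar exists for flashing-spot protocols.
* `response_map()` normalizes by the peak absolute response of the
  no-feedback variant, per map — so values read directly as
  enhancement (> 1) or suppression (< 1) relative to the feedback-free
  circuit.

## The synthetic movie generator

`generate_synthetic_movie()` stands in for naturalistic head-camera footage
in decorrelation analyses.  It emulates exactly two statistical properties
of natural movies: a power-law spatial power spectrum
$P(k)\propto|k|^{-\beta}$ with $\beta = 2$ by default (the classic
natural-scene exponent) and AR(1) temporal correlation with lag-one
coefficient 0.9 per frame at the grid's frame interval, with zero mean and
stationary variance.  It does **not** emulate occlusions, global motion
flow, non-Gaussian luminance histograms, or photographic content.  Tests
built on it therefore demonstrate the model's second-order filtering
behaviour (e.g. which feedback configuration decorrelates responses), not
performance on real footage.

## Problem sizes

Analyses and tests choose grids by what each quantity needs: temporal
impulse-response measures use the default 128 × 128 × 512 grid; area
summation and frequency tuning use a 512 px / 20 deg (tests: 256 px) static
grid so a 10-deg patch fits with margin; equivalence-with-oracle checks run
on 16³–32³ grids where direct DFT summation and direct convolution are
affordable; decorrelation runs use 32–64 px rasters with 512 frames.

## Limitations

Linear ON-pathway relay responses only: no rectification at the geniculate
level (responses may be negative), no spiking, bursting, adaptation,
contrast gain control, lagged cells, or X/Y nonlinearity.  Kernels are
space–time separable and circularly symmetric.  Boundaries are periodic.
Cortical responses, although available in principle from the same
formalism, are not exposed.
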
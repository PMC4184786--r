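---
title: "Methods: quantifying aggregate growth and mobility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying aggregate growth and mobility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbtrack)
```

This vignette explains the models and procedures implemented by `rbtrack`,
the assumptions behind them, and the design decisions taken where the
underlying measurement protocols left choices open.

## The mobility model

Russell bodies — micron-scale condensed protein aggregates in dilated ER
cisternae — move in a crowded, membrane-bounded environment. Their motion
is summarised by the time-averaged mean-square displacement of each
tracked cluster,

$$\mathrm{MSD}(k\,\Delta t) \;=\; \frac{1}{N-k}\sum_{i=1}^{N-k}
\bigl|\mathbf{r}_{i+k}-\mathbf{r}_i\bigr|^2,$$

fitted over the first 20 lags by the anomalous-diffusion power law

$$\mathrm{MSD}(t) = 4 D t^{\alpha}.$$

`D` (µm²/s) is the short-term diffusion coefficient — numerically, the MSD
prefactor at `t` = 1 s — and `α` the anomalous exponent: `α < 1` indicates
subdiffusive, constrained motion (obstacles, tethering, the ER membrane
itself), `α = 1` free Brownian motion, and `α → 2` directed transport.
Confinement is represented *only* through `α < 1`; no explicit corral or
reflecting boundary is modelled, because the fitted quantity is the power
law itself.

Overlapping displacement pairs are used in the time average (the standard,
lower-variance choice). Lags are computed up to a quarter of the track
length (`max_lag_fraction = 0.25`); beyond that the average rests on too
few pairs to be reliable.

### Fitting

The default estimator is ordinary least squares of $\log \mathrm{MSD}$ on
$\log t$: `α` is the slope and `D = exp(intercept)/4`. This choice is
exact on noiseless power laws (recovering generating parameters to
`1e-10` over `D ∈ [1e-4, 1e-1]`, `α ∈ [0.3, 2]`), is invariant to the
units the track was recorded in, and needs no starting values —
properties that matter when thousands of tracks are fitted unattended. A
nonlinear least-squares refinement on the linear scale (`method = "nls"`,
initialised from the log-log fit) is available; it weights large lags more
heavily and can differ slightly on noisy curves.

The model has **no constant offset term**. Static localisation error
$\sigma_{\mathrm{loc}}$ adds $4\sigma_{\mathrm{loc}}^2$ to the true 2D MSD
at every positive lag; absorbing it into the fit would change the model
being reported. The consequence, demonstrated in the test suite, is a
downward bias of the fitted `α` that grows monotonically with
$\sigma_{\mathrm{loc}}/\sqrt{4D\,\Delta t^{\alpha}}$ — users with
appreciable localisation error should interpret small fitted `α`
accordingly.

Tracks whose MSD is zero or negative anywhere in the fit window (possible
only for degenerate, e.g. perfectly stationary, input) are dropped and
counted, never imputed. Fitted exponents at or above the ballistic value 2
are flagged `superdiffusive`; values above 2.5 additionally warn, but are
not clipped, so drifting clusters remain visible in population tables
rather than being silently truncated.

Population summaries report mean ± SEM of `D` and `α` **over tracks** (the
track is the sampling unit, matching how track counts are reported in this
kind of experiment). Group comparisons default to the two-sided
Mann–Whitney test because `D` is strongly right-skewed across tracks; a
Welch t-test is available. Because "x-fold smaller on average" is
ambiguous for skewed quantities, `compare_conditions()` reports both the
ratio of group means and the ratio of group medians. Size–mobility
coupling uses Spearman rank correlation: the expected relation (larger
clusters diffuse more slowly) is monotone, not linear.

## The trajectory generator

Power-law MSD with stationary Gaussian increments is realised by 2D
fractional Brownian motion: independent per-axis fractional Gaussian noise
with Hurst exponent `H = α/2` and per-axis increment autocovariance

$$\gamma(k) = D\,\Delta t^{\alpha}\left(|k+1|^{\alpha} - 2|k|^{\alpha} +
|k-1|^{\alpha}\right),$$

so the per-axis MSD is $2Dt^{\alpha}$ and the 2D MSD exactly
$4Dt^{\alpha}$. Increments are simulated by Davies–Harte circulant
embedding — $O(n\log n)$ and exact in distribution — with a Cholesky
factorisation of the covariance matrix as fallback for lengths where the
embedding eigenvalues turn negative (the test suite verifies both paths
against $\gamma(k)$; for `α ∈ (0, 2]` at the lengths used here the
embedding always succeeds, and `α = 2` degenerates gracefully to a random
straight line). `α` outside `(0, 2]` is rejected: the covariance is not
positive semi-definite beyond the ballistic limit.

Optional deterministic drift models directionally moving clusters, and
optional static localisation noise (i.i.d. Gaussian per frame and axis)
models detection error. Every simulator is a pure function of its
configuration including the seed; populations derive per-track child seeds
from one parent seed.

Default simulation conditions mirror the live-cell acquisition this
package models: 300 frames at 0.5 s intervals, `D = 0.0045` µm²/s,
`α = 0.74`, and population sizes around 115 tracks.

## The image generator

Clusters are rendered as uniform disks (the optical section of a roundish
aggregate), convolved with a Gaussian PSF, scaled to a peak photon count,
offset by a background, and degraded with Poisson shot noise (optionally
plus Gaussian read noise). Disk edges are anti-aliased with a one-pixel
linear ramp before blurring. In the two-colour mode the red channel is a
disk of the core diameter and the green channel a disk larger by the
configured `shell_growth_fraction`; the green channel is rendered as a
**filled disk** by default — the FWHM of a filled disk is what the growth
statistic compares — with an annulus mode kept for visual fidelity to
onion-like two-colour images.

Defaults are 0.1 µm pixels and a PSF σ of 0.085 µm (≈ 200 nm FWHM lateral
resolution, typical of a confocal at high NA). These are stated
assumptions of the simulation, configurable everywhere and hard-coded
nowhere in the analysis algorithms.

What the generator deliberately does **not** emulate: axial (3D)
structure, photobleaching (negligible over the few-hundred-frame movies
modelled here), aggregate nucleation or fusion kinetics, intracellular
background structure, and camera-specific noise beyond
Poisson + Gaussian. Passing tests on this synthetic data therefore
validate the *measurement pipeline* — sizing, detection, linking,
fitting — not the biological realism of any particular movie; on real data
the dominant additional error sources are out-of-focus drift, neighbouring
structures on the profile line, and motion blur.

## FWHM morphometry

The cluster diameter is the full width at half maximum of an intensity
profile through the cluster centre. The implementation automates what is
traditionally a manual measurement:

* **Profile extraction.** Samples at pixel pitch along the line by
  bilinear interpolation. The background is the median of the outer 10% of
  samples at each end of the line — a local rule, robust to neighbouring
  clusters, used because acquisition protocols rarely state one.
* **Half-maximum crossings.** The level is `background + (peak −
  background)/2`; crossings are located by linear interpolation between
  bracketing samples, and when noise creates several crossings the two
  *nearest the peak* are used. Linear interpolation gives
  better-than-pixel precision without assuming a profile model; on a
  Gaussian of σ = 2 px it is accurate to about 1%.
* **Angle averaging.** The operator-chosen diameter direction is replaced
  by the mean FWHM over `K = 8` evenly spaced directions through the
  intensity-weighted centroid (red channel), which is unbiased for round
  clusters and removes operator dependence; a single fixed angle remains
  available.
* **The growth statistic.** `rel_increase = (d_g − d_r)/d_r`, measured on
  the same lines in both channels. PSF broadening inflates both diameters
  and largely cancels in the ratio; on rendered ground truth with a 16%
  shell the pipeline recovers 0.16 within ±0.02 (noise-free) and ±0.03
  (Poisson noise, 99 clusters).
* **Summary.** Mean ± SEM, by default over clusters; per-cell aggregation
  first (SEM over cells) is offered because both units are defensible when
  several clusters per cell are measured, and published reports do not
  always state which was used.

## Detection and linking

Per-frame detection is Laplacian-of-Gaussian filtering at the scale
matched to the expected diameter ($\sigma = d/(2\sqrt{2})$), strict local
maxima above a robust threshold (`median + 5·MAD` of the response, floored
at 2% of the maximum response so faint filter sidelobes are rejected in
low-noise frames), greedy non-maximum suppression at half the expected
diameter, and sub-pixel refinement by a three-point quadratic fit along
each axis (better than 0.2 px on rendered ground truth).

Frame-to-frame linking minimises total squared displacement by optimal
bipartite assignment (Hungarian algorithm) over a cost matrix augmented
with track-termination and track-birth alternatives at the gate cost — so
a spot further than `max_displacement` from every track end starts a new
track rather than forcing a bad link. This is deterministic and invariant
to spot order, unlike greedy nearest-neighbour linking (with which it
provably agrees when the gate is smaller than half the inter-spot
distance). There is **no gap closing**: bright aggregates rarely blink,
and gap parameters would be unconstrained guesswork. The length filter is
strict — "longer than 150 frames" keeps tracks with at least 151 points —
and every dropped track is counted in the run report.

Coordinates follow the convention: pixel centres at integer (column, row),
x along columns, physical position = (index − 1) × pixel size, all
analysis in µm and seconds.

## Numerical and testing choices

* Fit window: 20 lags (the standard short-lag window for this protocol);
  tracks must provide at least that many lags after the
  `max_lag_fraction` cut, i.e. ≥ 80 gap-free frames.
* TIFF I/O stores photon counts as 16-bit pages; round-trip error is below
  half a count for the ranges the renderer produces.
* The test suite's statistical checks derive their tolerances from the
  Monte-Carlo error measured across independent replicates (not from fixed
  magic numbers), and the brute-force oracles (double-loop MSD, upsampled
  FWHM scanner, exhaustive assignment enumeration) are implemented
  independently of the fast paths they validate.
* Problem sizes in the test suite — e.g. 20 replicate populations of
  115 × 300-frame tracks for bias checks, 400 replicates of 20-track
  groups for the type-I-error calibration, 99 cluster pairs for the
  growth scenario — were chosen to keep each statistical assertion's
  Monte-Carlo error well below the tolerance it checks while the whole
  suite runs in a couple of minutes on one core.

## Known limitations

* The subdiffusion model is a pure power law; transient behaviours
  (corralled → free crossover, motion-state switching) are out of scope.
* Localisation error is a documented bias, not an estimated parameter; if
  it matters, estimate it separately (e.g. from fixed samples) and
  simulate its effect with `loc_noise_sd`.
* Linking assumes clusters stay resolvable; merging/splitting events are
  not modelled and will fragment tracks.
* FWHM sizing assumes an isolated, roughly round cluster; strongly
  elongated or touching clusters violate the angle-averaging assumption
  (the per-angle option exists for such cases).
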
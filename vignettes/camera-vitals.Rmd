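---
title: "Camera-based vital signs: model, processing chain, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-based vital signs: model, processing chain, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A camera pointed at a person records, besides the scene itself, two tiny
physiological modulations of brightness: the cardiac blood volume pulse
(BVP) changes how much light the skin absorbs on every heartbeat, and
chest/abdomen motion changes the reflected light path on every breath.
`vitalcam` recovers heart rate (HR) and respiration rate (RR) from a
*single-channel* 8-bit image sequence — monochrome night footage included —
and, critically for alarm applications, decides whether the scene contains
a live subject at all, so that a photograph or a cartoon on a screen does
not masquerade as a healthy patient.

The observed signal is one number per frame: the spatial mean brightness
of a region of interest (ROI), a face patch for the cardiac signal and a
chest band for the respiratory one. At a typical 15 fps and over a 30 s
window this is a short, noisy, drifting series in which the pulse is often
invisible to the eye.

## From one series to a state space: delay embedding plus ICA

A single observed series $x(t)$ is treated as one coordinate of a
multidimensional dynamical system (the cardiorespiratory system). With
sampling interval $\tau_s = 1/f_s$, delay $d$ and embedding dimension $m$,
the delay-coordinate embedding stacks lagged copies into an
$m \times n$ matrix

$$X_{ij} = x(j + i\,d), \qquad n = N - (m-1)\,d,$$

which by the embedding theorem reconstructs the state space of the
underlying system from the single observable. The package follows the
fixed choice $m = 3$, $d = 1$; $n$ is always maximal for the window so no
data are discarded.

The rows of $X$ are then treated as a linear mixture $X = A Y$ of
independent sources and unmixed with FastICA ($Y = W X$): the fixed-point
iteration with the kurtosis contrast ($g(u) = u^3$), symmetric
decorrelation, tolerance $10^{-6}$, at most 500 iterations, and a
seed-controlled random initialization so every run is reproducible. Among
the $m$ components, the physiological one is selected as the row whose raw
periodogram has the highest *peak power-density ratio*

$$R = \frac{\max_k P_k}{\sum_k P_k}, \qquad f_k \in (0, \min(8, f_s/2)]\ \text{Hz},$$

i.e. the most spectrally concentrated component; ties break to the lowest
index and the component's sign is chosen so its skewness is positive (the
systolic upstroke points up).

Two numerical details are worth recording. First, the fixed-point update
is accepted as converged when either the usual one-step criterion or the
same criterion against the state two iterations back passes: on nearly
sinusoidal input the two noise components span a degenerate, near-Gaussian
subspace in which the update settles into a period-2 cycle whose two
states are equally valid demixings. Second, when the update has not
settled after the iteration cap — which happens precisely in that
degenerate situation, where a continuum of equivalent solutions exists —
the current estimate is returned with a warning rather than an error (an
error mode is available via `on_fail = "error"`). The reconstruction
identity $A Y = X_\mathrm{centered}$ holds to machine precision in every
case and is tested.

## Conditioning and rate extraction

Each analysis window passes through, in order:

1. **Optional highpass** (zero-phase, forward–backward 4th-order
   Butterworth). Only used where a strong low-frequency component swamps
   the target: the mouse preset filters at 5.8 Hz because whole-body
   respiratory motion buries the cardiac signal.
2. **Smoothness-priors detrending**: the trend is
   $t = (I + \lambda^2 D_2^\top D_2)^{-1} x$ with $D_2$ the second
   difference operator; the series minus its trend is kept. $\lambda$ is
   dimensionless; defaults $\lambda = 20$ (cardiac) and $\lambda = 300$
   (respiratory), chosen for 15 fps human data and exposed as
   configuration since the appropriate stiffness scales with the frame
   rate. The solve uses the banded sparse structure and is tested against
   a dense linear-solve oracle at $10^{-8}$.
3. **Normalization** to exact zero mean and unit *population* (1/N)
   variance. The convention is arbitrary — everything downstream is
   scale-invariant — so one is fixed and tested.
4. **Embedding, FastICA, component selection** as above.
5. **Moving average** (centered, shrinking at the edges): 5 points for
   the cardiac wave, 13 for the respiratory wave.
6. **Three-layer autocorrelation**: the normalized biased autocorrelation
   (nonnegative lags, unit lag-0) applied three successive times. Each
   layer sharpens periodic structure against residual wideband noise and
   preserves the dominant frequency to within one bin (tested). The
   construction "apply the operator three times" is one reading of a
   procedure whose details are not fully pinned down by its name;
   alternatives (e.g. lag-truncated repeated autocorrelation) would
   differ only in edge behavior. One layer is tested against an
   $O(N^2)$ lag-sum oracle at $10^{-9}$.
7. **FFT with zero padding** to the next power of two at least $8N$: a
   30 s window at 15 fps is interpolated onto a grid finer than 4 mHz,
   enough to report a peak such as 2.15 Hz from a 450-sample record. The
   one-sided spectrum is scaled so that total power equals time-domain
   energy (Parseval, tested).
8. **Band-restricted peak search** and conversion rate = 60·f. Search
   bands are per-species presets (human BVP 0.7–4 Hz, human RW
   0.1–0.8 Hz, mouse BVP 5.8–14 Hz, mouse RW 1.5–5 Hz, analogous
   zebrafish/pig presets), all overridable; the total-power band for
   $R$ is always 0–8 Hz.

Windows slide with a default stride of 1 s and length 30 s, giving
quasi-continuous rate traces; a window in which the chain cannot run
(constant input, say) yields a flagged `NA` row rather than an error.

## Liveness: the ratio-variation classifier

An inanimate subject — a magazine photo, a painting, a screen — still
produces an observed series: drift, flicker and sensor noise. Its selected
"source" is wideband, and smoothing reshapes a wideband spectrum much more
than it reshapes a spectrum dominated by one physiological peak. The
*ratio-variation* statistic quantifies this:

$$\nu = \frac{|R_\mathrm{pre} - R_\mathrm{post}|}{R_\mathrm{post}},$$

where $R_\mathrm{pre}$ and $R_\mathrm{post}$ are the peak power-density
ratios of the selected source before and after the moving-average
smoothing. For a live subject the dominant peak survives smoothing and
$\nu$ is small; for noise the ratio changes substantially and $\nu$
scatters around 0.5.

Two published reference densities classify a measurement by pointwise
comparison: live $\nu \sim$ Gamma($a = 1.5335$, $b = 0.0599$), inanimate
$\nu \sim$ N($\mu_o = 0.4905$, $\sigma_o = 0.1434$); the verdict is "live"
iff $f_T(\nu) > f_F(\nu)$, ties conservatively going to "inanimate". The
normalization of $\nu$ by $R_\mathrm{post}$ rather than $R_\mathrm{pre}$
is a deliberate design choice: the defining formula is not recoverable
from its source at full precision, and of the two minimal readings only
the $R_\mathrm{post}$ denominator is consistent with the reference
densities — Monte-Carlo at the reference settings (15 fps, 10 s windows,
5-point smoothing) puts noise $\nu$ near 0.5 under this form and near 1.8
under the other, where both densities underflow and the comparison
degenerates. The statistic is isolated in `ratio_variation()` so the form
can be swapped in one place.

`fit_pds()` refits both densities from labelled samples (Gamma by maximum
likelihood, Gaussian by moments, Kolmogorov–Smirnov goodness-of-fit
reported), which is the recommended path whenever the acquisition chain
differs from the one the shipped constants were fitted on.

The *accumulated rule* (`classify_accumulated()`) sums each density over
three successive measurements (10 s windows taken 5 s apart) and compares
the sums. In the bundled synthetic study this robustly cuts the
false-negative rate roughly in half relative to single-window
classification; its effect on the false-positive rate is *not* reliably an
improvement under the synthetic conditions, because the peaked live Gamma
lets one live-looking window dominate the three-window sum — see
Limitations.

## The synthetic scene generator

Real recordings with reference ECG are not shippable, so every stage is
validated against a generator with known ground truth. A scene is

* baseline brightness (default 128 of 255) plus, inside a "skin" ROI, a
  cardiac waveform — fundamental plus a 10% second harmonic, so peak
  selection faces a realistically asymmetric pulse — and, inside a
  "chest" ROI, a sinusoidal respiratory waveform (default amplitudes 3
  brightness units);
* a slow illumination drift (sinusoid, default amplitude 5, period 30 s,
  i.e. below 0.05 Hz), exercising the detrender without committing to a
  trend family;
* an AR(1) illumination flicker common to the whole frame (default sd 2,
  lag-one coefficient 0.85, concentrating its power below roughly
  0.4 Hz). The flicker term is what gives no-signal scenes the
  low-frequency-dominated wideband character of real indoor footage; its
  two parameters were set by matching the ratio-variation statistics of
  inanimate synthetic scenes to the reference inanimate density
  ($\mu_o \approx 0.49$) at the reference settings, and then frozen;
* independent white sensor noise per pixel (default sd 1), with
  signal-to-noise defined as $\mathrm{amp}^2 / (2\,\mathrm{noise\_sd}^2)$;
* 8-bit quantization (round, clip to 0–255) after summing components.

Determinism is strict: one seed fixes phases, flicker, and noise, and the
1-D series generator and the frame renderer share their phase and flicker
draws, so the ROI mean of a rendered scene reproduces the 1-D series up to
quantization. An inanimate scene is the same construction with both
physiological amplitudes forced to zero.

What the generator does *not* emulate: subject motion and re-lighting,
auto-gain compression (worth disabling on real cameras for nighttime
work), rolling-shutter artifacts, spatially structured noise, and
photorealistic skin. Passing the synthetic studies therefore demonstrates
the correctness and noise robustness of the signal chain, not performance
under motion artifacts.

## Bundled validation studies and problem sizes

`synthetic_recovery_study()` draws 100 subjects (30 s at 15 fps, HR
uniform 50–110 bpm, RR 10–25 breaths/min, SNR 3–10) and reports recovery
errors; the acceptance gate is HR within ±2 bpm and RR within
±1 breath/min in at least 95% of subjects. `synthetic_liveness_study()`
mirrors the train-then-test protocol of the reference evaluation: the
densities are fitted on an independent training ensemble (100 subjects per
class) and the single-window and accumulated rules are then scored on 200
test subjects per class, three 10 s windows each, with live
signal-to-noise spanning 1–6 so that borderline windows actually occur.
These sizes keep the full suite and the acceptance script in the
tens-of-seconds range on one core while leaving the Monte-Carlo margins
comfortable.

## Limitations

* **Accumulated-rule false positives.** With densities as peaked as the
  fitted live Gamma, summing over three windows behaves on the inanimate
  side like an OR over a lower threshold: it strictly reduces false
  positives only when the inanimate $\nu$ distribution has a very thin
  left tail. The reference densities satisfy this (verified
  distributionally in the test suite); the synthetic signal-level
  ensemble does not quite, because ICA component selection on stochastic
  spectra occasionally produces a smoothing-invariant low-frequency peak.
  Treat the accumulated rule as a false-negative (missed-subject) guard
  first.
* **Frame-rate bound accuracy.** All rates come from spectral peaks of
  short windows; zero padding interpolates the grid but cannot beat the
  underlying resolution trade-off. Beat-to-beat intervals and HRV are out
  of scope.
* **Fixed ROIs per run.** Detection boxes (from any external detector)
  are consumed as rectangles; the ROI is not re-tracked within an
  analysis window.
* **Detrending stiffness is frame-rate dependent.** The shipped
  $\lambda$ defaults suit 15 fps; high-speed (e.g. 80 fps small-animal)
  recordings should scale them, which is why they sit in
  `rate_config()` rather than in the algorithm.
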
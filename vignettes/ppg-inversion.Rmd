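---
title: "Detecting and quantifying PPG signal inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying PPG signal inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7, fig.height = 4)
library(ppginv)
library(dplyr)
```

## The problem

In reflectance photoplethysmography (PPG) the detected light intensity
normally *falls* during systole: the arriving pressure pulse increases local
blood volume and absorption. Signal *inversion* is the anomaly in which
intensity instead rises with systole, so the pulse waveform is flipped and
tracks the arterial blood pressure curve directly. Inversion is rare but
matters wherever pulse morphology or fiducial timing is the measurand —
pulse wave analysis, pulse arrival/transit time, cuffless blood pressure
estimation — and it is most likely when a reflectance probe sits near a
larger artery, under varying contact pressure, across LED wavelengths.

`ppginv` implements a per-pulse inversion classifier with two independent
layers, the recording-level statistics built on it, and a synthetic
multi-wavelength generator with per-beat polarity ground truth so that the
whole chain can be validated without access to clinical recordings.

## Preprocessing

Each raw channel is negated first (so a normal pulse points upward like an
arterial pressure wave), then band-limited:

* **Baseline high-pass.** The contract is 60 dB attenuation at and below
  0.05 Hz with at most 0.5 dB ripple at and above the 0.1 Hz passband edge.
  We apply a zero-phase Butterworth-magnitude gain
  $G(f) = 1/(1+(f_c/f)^{2m})$ in the frequency domain on an
  odd-reflection-padded copy of the signal; the order ($2m = 16$) and cutoff
  ($f_c \approx 0.077$ Hz) are computed from the two constraints. Applying
  the gain directly in the frequency domain is exactly linear, introduces no
  phase distortion (fiducial timing is preserved), and avoids the numerical
  fragility of time-domain recursions at a cutoff four decades below the
  sampling rate. The price is a boundary effect governed by the padding:
  time-shift equivariance holds on interior samples to well under a percent
  of signal range, but not bit-exactly (the test suite pins both this and
  the exact equivariance of the smoothing stage).

* **Savitzky–Golay low-pass.** Local least-squares polynomial smoothing with
  polynomial order 20 and frame length 999. We build the projection kernel
  from a QR factorisation of the local design matrix on abscissae scaled to
  $[-1, 1]$, which keeps the degree-20 fit well-conditioned; interior
  samples are produced by convolution with the central projection row and
  the first/last half-frames by evaluating the first/last full-frame fit at
  the off-center positions, so no samples are discarded. Polynomials of
  degree ≤ 20 are reproduced to ~1e-14 relative. At 800 Hz this filter is
  flat (< 1e-6 dB) through 2 Hz, −1.1 dB at 5 Hz and −19 dB at 10 Hz: with a
  frame of 999 samples the paper-level parameters imply a pass band that
  accommodates the cardiac fundamental and first harmonics, not the full
  0–10 Hz band, and the property tests assert the flat band the filter
  actually has.

Every stage is linear and odd, so `prepare(-x) = -prepare(x)` holds
bit-for-bit — the foundation of the negation-duality tests.

## The two-layer classifier

**Candidates.** All strict local extrema are gathered; a plateau contributes
one candidate at its midpoint. Candidates within 240 samples of either end
are dropped (their analysis windows would truncate). Each candidate must
then *dominate* its neighbourhood: a peak fails if any sample within ±150
samples exceeds it (troughs symmetrically). Ties do not disqualify — the
comparison is strict. The ±150-sample reading (rather than 150 total) is
the conservative interpretation and matches the physiological refractory
scale at 800 Hz (~0.19 s).

**Layer 1 — systole/diastole symmetry.** A real systolic endpoint is
preceded by the steep systolic limb and followed by the slower diastolic
one. For each verified candidate we compare the mean absolute first
difference over the 240 samples (~0.3 s) before the reference point against
the 240 samples after it; the criterion passes iff the preceding tangent is
strictly greater. A tie carries no systole/diastole evidence and fails.
Passing peaks are labelled $a_i = +1$ (non-inverted), passing troughs
$a_i = -1$ (inverted).

**Layer 2 — triangulation sharpness.** Each verified candidate is
triangulated with its nearest local extremum of the *same* kind on each side
that was not itself retained as a verified candidate (dicrotic peaks,
notches, ripples). With $P$ the candidate vertex and $L, R$ its neighbours,
the law of cosines gives
$\cos\theta = (a^2 + b^2 - c^2)/(2ab)$ at $P$: positive for sharp (acute)
vertices, negative for blunt (obtuse) ones. Time is measured in samples and
intensity as the per-series z-score; this makes the angle dimensionless and
invariant to gain, offset, and time translation (and symmetric under
negation, so inverted and normal pulses are treated even-handedly). A
recording whose troughs are on average sharper than its peaks is phased
*inverted* by this layer. When no neighbour extrema exist on one side the
candidate simply carries no angle; if no candidate carries an angle the
layer reports *indeterminate* and only the symmetry layer is evaluated.
Whether the layer mean should be taken over $\theta$ or $\cos\theta$ is
underdetermined; we use $\cos\theta$ because the sign convention is defined
on it and it is bounded.

## Recording statistics

With $N$ symmetry-passing pulses and labels $a_i$:

$$\mu = \frac{1}{N}\sum_i a_i, \qquad \mathrm{DOI} = \frac{1-\mu}{2} \in [0,1]$$

A recording is classified inverted iff DOI strictly exceeds the threshold
(default 0.25). The *occurrence of inversion* of a measurement cell
(position × pressure × LED) is the fraction of analyzable recordings
classified inverted. Two flags accompany every estimate and never alter it:

* **noise** — $|\mu| < 0.3$: mixed or noise-corrupted signals drive the mean
  label toward zero. (The screen is applied to $|\mu|$, not to DOI: an
  inconsistent signal has DOI near 0.5, not near 0, so the $|\mu|$ reading
  is the only self-consistent one.)
* **disagreement** — the two layers assign opposite phases. The symmetry
  layer is reported as primary; exclusion is a user decision via the
  config's `exclude_source_ids`, mirroring a flag-then-review workflow.

Recordings with no symmetry-passing pulses, and recordings the user
excludes, leave every OOI denominator; empty cells are reported missing,
never imputed as zero.

## The synthetic generator

`simulate_recording()` concatenates beats rendered from a two-lobe template
(half-cosine upstroke over 15 % of the period, exponential-like decay,
Gaussian dicrotic wave at 45 % of the period with relative amplitude 0.2),
jitters beat periods (SD 3 % by default), assigns each beat a polarity
(contiguous block with a deterministic count, or i.i.d. Bernoulli), and adds
sinusoidal baseline wander (0.5 × amplitude over 30 s), white noise
(0.02 × amplitude) and optional motion artifacts. Polarity is per beat and
per LED channel — a measurement can be inverted on one wavelength and
normal on another — while beat timing is shared across channels. Signals
are emitted in raw sensor convention (normal systole = intensity dip) so
the preprocessing negation is exercised end to end. Defaults follow the
acquisition protocol the generator emulates: 90 s at 800 Hz, 60 bpm, four
LED channels, and a 12-participant × 11-position × 3-pressure grid (1584
channel-recordings). Contact force and temperature metadata are drawn
uniformly within the observed ranges of the study-conditions table
(`study_conditions()`).

What the generator does *not* emulate: optical tissue physics, wavelength-
dependent penetration, venous pulsation, respiratory modulation, sub-beat
polarity morphing, or realistic artifact morphology. Passing tests
demonstrate that the algorithm recovers planted ground truth under
morphology it was designed to exploit — steep upstroke, slower decay —
with realistic noise and drift; they say nothing about performance on
pathological waveforms or heavy motion contamination.

```{r pipeline}
rec <- simulate_recording(sim_plan(fraction_inverted = 0.3), seed = 42)
fit <- analyze_pulses(prepare_channel(rec, "ir"))
glance(fit)
```

## Numerical and design choices

* **Strictness.** Dominance ties pass; symmetry ties fail; the DOI
  classification boundary (0.25) itself is *not* inverted. All three are
  deliberate readings of strict inequalities.
* **Indexing.** In-memory tibbles use R's 1-based `sample`; CSV files use a
  0-based `sample_index` column. The readers/writers own the conversion.
* **Plateaus.** One candidate at the plateau midpoint
  (`floor((start+end)/2)`); plateau extrema are not eligible as
  triangulation neighbours.
* **Filter order of operations.** Negation, then high-pass, then smoothing.
  All three are linear, so the composite response is order-independent;
  the order is fixed for reproducibility only.
* **Thresholds.** DOI threshold 0.25 and noise screen 0.3 are the
  validated defaults; both are exposed in `run_config()` / `metric_params()`
  and lowering the DOI threshold makes the binary classification stricter.

## Problem sizes in the test suite

The round-trip acceptance property runs 200 seeded 90 s recordings at
800 Hz / 60 bpm with noise SD 0.02 × amplitude and asserts 100 % per-pulse
polarity accuracy and per-recording |DOI − truth| ≤ 0.05. Properties that
are invariant to recording length (negation duality, the brute-force
candidate oracle, planted-grid round trips) use 20–30 s recordings or
series of ≤ 2000 samples, which keeps the default suite fast without
weakening any assertion.

## Limitations

* The triangulation layer needs intermediate extrema; on perfectly smooth
  pulse trains without dicrotic structure it returns *indeterminate* and
  only the symmetry layer decides.
* The boundary behaviour of the high-pass is padding-dependent within
  roughly 10 s of each end of a recording; at the default 90 s length this
  leaves the bulk of every recording unaffected, but estimates from very
  short series lean on edge-handled samples.
* Flags are surfaced, never auto-resolved; a workflow that ignores the
  disagreement flag inherits the symmetry layer's errors on signals where
  the two layers conflict.
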
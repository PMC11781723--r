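---
title: "Camera-based blood pressure estimation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-based blood pressure estimation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(videobp)
```

## The measurement problem

Cuff-based sphygmomanometry is accurate but episodic, and in many field
settings no cuff is available at all. `videobp` implements a non-contact
estimator that needs only an ordinary RGB camera: a short video of a seated
subject with face and open palm in the same frame, one full-length standing
photo, and three demographic numbers (height, weight, age). From these it
produces one systolic and one diastolic pressure per video, in mmHg.

The physical route is pulse transit time (PTT). The same cardiac ejection
reaches the face and the hand at slightly different times because the
arterial paths from the heart differ in length. How fast the pressure pulse
travels — the pulse wave velocity (PWV) — depends on arterial stiffness,
and stiffness depends on the distending pressure. Measuring the face-to-hand
delay therefore carries pressure information, provided the path-length
difference and the vessel's geometry are known.

## The pressure model

Three relations are combined:

1. **Moens–Korteweg**: $\mathrm{PWV}^2 = E h / (\rho D)$, where $E$ is the
   arterial elastic modulus, $h$ the wall thickness, $\rho$ blood density
   and $D$ the lumen diameter.
2. **Exponential pressure–elasticity law**: $E = E_0 e^{\alpha \, BP}$.
3. **Path geometry**: $\mathrm{PWV} = L / \mathrm{PTT}$, with $L$ the
   difference between the heart-to-face and heart-to-hand vessel lengths.

Eliminating $E$ and $\mathrm{PWV}$ and solving for pressure gives

$$ BP \;=\; -\frac{2}{\alpha}\ln \mathrm{PTT}
   \;+\; \frac{1}{\alpha}\ln\!\frac{\rho\,L^2\,D}{h\,E_0}. $$

Systolic pressure uses the peak-to-peak transit time (`ptt_s`), diastolic
the valley-to-valley transit time (`ptt_d`), each with its own diameter
($D_s$, $D_d$; equal by default, see below). `invert_ptt()` is the exact
algebraic inverse,
$\mathrm{PTT} = L\sqrt{\rho D/(h E_0)}\,e^{-\alpha BP/2}$, and
`estimate_bp(invert_ptt(x)) = x` holds to machine precision — this
round-trip, together with the identity
$\mathrm{PWV}^2 \rho D = h E_0 e^{\alpha BP}$, carries the correctness
burden for the model code, and both are asserted in the test suite.

### Constants, units and the $D/h$ ratio

`model_constants()` fixes $\rho = 1060$ kg/m³, $E_0 = 1005$ and
$\alpha = 0.017$ per mmHg — standard literature values with no meaningful
demographic variability. The demographic regressions for diameter and wall
thickness,

$$ D = -0.258 + 0.029\,H_{cm} + 0.006\,A_{yr} + 0.036\,\mathrm{BMI},
\qquad h = 0.25 + 0.005\,A_{yr} + 0.005\,\mathrm{BMI}, $$

return values on a millimetre scale (about 5.5 and 0.58 at typical adult
inputs). The model is deliberately agnostic about their absolute unit:
$D$ and $h$ enter the pressure equation and its inverse *only through the
ratio* $D/h$ (inspect the formulas above), so any common length unit
cancels. Only $L$ must be in metres; the package converts centimetres to
metres exactly once, inside `build_parameters()`. The absolute pressure
scale is then set by $E_0$, whose published value we use as-is; the exact
round-trip and ratio identities are unit-exact and are what the tests pin
down.

### Two estimator variants

* **demographic** — per-subject $L$ from the full-length image, $D$ and
  $h$ from the regressions above;
* **fixed** — literature constants for everyone: $L = 0.2$ m, arterial
  radius $0.005$ m (so $D = 0.01$ m), $h = 0.001$ m.

At equal transit time the two differ by exactly
$\frac{1}{\alpha}\ln\frac{L^2 D/h}{L_f^2 D_f/h_f}$, which the evaluation
module uses as an algebraic cross-check. A systolic-to-diastolic diameter
ratio is exposed (`ds_ratio`, default 1) because the demographic pathway
supplies a single diameter; distinct systolic/diastolic diameters are a
modelling refinement we deliberately leave at parity by default.

## From video to transit time

1. **Tracking.** A pluggable backend maps each frame to face and hand
   landmark sets. Any dense tracker can serve; the package bundles a
   deterministic fixture provider (for synthetic clips) and a JSON-lines
   adapter for landmarks precomputed by an external detector. Frames where
   either site fails are marked invalid; runs of invalid frames longer
   than 2 s abort with a quality error (a silent cut would tear the pulse
   trace), shorter gaps are dropped and bridged by linear interpolation on
   the nominal frame grid.
2. **Regions of interest.** Fixed, documented landmark-index subsets bound
   the forehead and the palm centre. Because vertices are landmarks, ROIs
   translate and scale with the subject automatically.
3. **Spatial averaging.** Per-frame RGB means over the ROI interior
   (point-in-polygon on pixel centres, masks memoised per polygon).
4. **Chrominance projection (CHROM).** Within 1.6 s Hann windows at 50%
   overlap, channels are normalised by their window means and combined as
   $X = 3R_n - 2G_n$, $Y = 1.5R_n + G_n - 1.5B_n$,
   $S = X - \frac{\sigma_X}{\sigma_Y} Y$, then overlap-added with the
   window weight divided out. The mean normalisation makes the output
   exactly invariant to common rescaling of all channels (illumination
   level, exposure). The projection's sign is arbitrary, so the output is
   oriented to positive skewness: a pulse waveform dwells near its
   diastolic baseline, so the correct orientation is right-skewed. Without
   a consistent orientation, peak and valley labels — hence systolic and
   diastolic transit times — would swap unpredictably.
5. **Band-pass.** Butterworth 0.25–15 Hz, total order 4, applied
   forward-backward (`signal::filtfilt`) so the filter adds no group
   delay — PTT is a timing measurement, and both sites share one filter
   design. The signal is demeaned before filtering (the DC step at the
   edges is the dominant edge-transient source; a constant input maps to
   exactly zero). At frame rates at or below 30 fps the 15 Hz cutoff
   would sit at Nyquist; it is clipped to $0.45 f_s$ with a warning.
6. **Events and pairing.** One second is trimmed from each end of the
   filtered signals (filter transients), then peaks are local maxima above
   0.3 signal standard deviations with a 0.4 s refractory spacing (caps
   heart rate at 150 bpm); valleys are peaks of the negated signal. Event
   times get a three-point parabolic sub-sample refinement — a pure
   function of the three local samples, so exactly-shifted signals yield
   exactly-shifted events. Face and hand trains are matched by greedy
   nearest-neighbour pairing within half the median inter-beat interval
   (prevents cross-beat mispairing), ties broken toward the earlier hand
   event. The transit time is the mean absolute paired difference, by the
   magnitude convention: the model pairs a positive PTT with a positive
   path-length magnitude $L$, and which site leads is not used. At least 5
   pairs are required; a zero transit time is flagged (pressure is
   undefined there), not silently propagated.

## Anthropometric geometry

The full-length standing image ties pixels to centimetres through the
measured height: $p = \mathrm{height}_{px} / \mathrm{height}_{cm}$. The
heart-to-face and heart-to-hand pixel distances, divided by $p$, give
centimetre path lengths and $L = |\mathrm{dist}F_{cm} -
\mathrm{dist}H_{cm}|$. Because $p$ absorbs the camera distance, $L$ is
invariant to where the camera stood — the package makes this invariance
*bit-exact* for integer pixel scales by two numerical choices: anchor
arithmetic uses only dyadic fractions (the heart anchor sits one-eighth of
the way from the shoulder midpoint toward the hip midpoint — the fraction
is anatomically arbitrary, and a dyadic value keeps the arithmetic exact in
binary floating point), and the pose-fixture generator quantises
coordinates to 0.25 cm with the heart-to-wrist offset laid out in 5:12:13
proportion so every derived distance is exactly representable. The anchors
(heart, face, hand) are this package's convention, documented in
`pose_anchor_table`; distances are straight-line, with arterial tortuosity
absorbed into the proportionality assumption.

## What the synthetic generators emulate

No public recording corpus exists for this face-plus-hand protocol, so the
package generates its own inputs, with ground truth, at the study's stated
conditions:

* **Pulse pairs** — a two-Gaussian per-beat waveform (sharp systolic wave
  plus a dicrotic bump at +0.35 s, $\sigma = 0.18$ s, so the decay runs
  into the next upstroke and the diastolic foot is V-shaped rather than a
  flat plateau, where valley timing would be ill-defined); lognormal beat
  jitter with 3% coefficient of variation; hand = face delayed by the
  transit delay. Integer-sample delays are implemented as exact sample
  shifts so pure-delay recovery tests are exact; distinct peak/valley
  delays warp the hand signal through a slowly varying delay field.
* **Skin videos** — base skin tones multiplicatively modulated by the
  pulse inside two non-overlapping patches, with per-channel strengths
  (green strongest, roughly 0.3/0.8/0.5), because a channel-identical
  modulation is pure common-mode intensity — exactly the component CHROM
  cancels — and would carry no recoverable pulse. When written to 8-bit
  PNG frames, a static spatial dither is applied: the pulsatile amplitude
  is below one grey level, and dithering lets the ROI average resolve it
  (the standard dithered-quantisation argument).
* **Pose fixtures** — stick figures from standard body-segment
  proportions, exact by construction as described above.
* **Cohorts** — demographics and true pressures drawn from per-country
  truncated normals matching the reference field cohort's group statistics
  (half India, half Sierra Leone; gender by observed proportion; diastolic
  resampled until pulse pressure ≥ 10 mmHg), geometry from height with 3%
  lognormal individual variation, and transit times *derived from the true
  pressures* by the closed-form inversion — so the cohort is exactly
  model-consistent and the demographic-variant estimator must recover
  truth to machine precision, while the fixed variant diverges by the
  algebraic identity above.

What the generators do **not** emulate: motion, occlusion and tracking
noise; specular reflection and colour-channel crosstalk of real sensors;
ballistocardiographic artefacts; physiological PTT–pressure variability
beyond the model (wave reflections, vasomotion); correlations between
height and weight in the cohort sampler. Passing tests therefore
demonstrate that the pipeline implements its model faithfully and recovers
known truth under its own assumptions — not that the model's absolute
accuracy transfers to real subjects.

## Evaluation statistics

`evaluate_bp()` and `compare_variants()` reproduce the agreement machinery
used for estimator comparison: mean absolute error; Bland–Altman mean
difference with 95% limits of agreement (oriented truth − estimate);
intraclass correlation in the two-way absolute-agreement single-measure
form ICC(A,1) — chosen because it penalises systematic offsets, which a
consistency ICC would forgive; and the two-sample Kolmogorov–Smirnov test
with asymptotic p-values (adequate at cohort sizes of hundreds). The 0.05
significance level is an annotation on the report, never a gate. All four
statistics are checked against independent brute-force recomputation in
the tests.

## Problem sizes and determinism

The test suite and the acceptance script run on deliberately compact
problems chosen as representative of the method's scales: 48×64 px clips
of 10–16 s at 60 fps, 30 s signal pairs, 50-case delay sweeps, and
cohorts of 400 subjects (the reference study's size). Every stochastic
step is a pure function of an integer seed; identical inputs give
bit-identical outputs end to end.

## Known limitations

* Absolute pressure scale inherits the published constants' implicit
  units; no recalibration against cuff references is attempted.
* One PTT per video: no beat-by-beat pressure series, no waveform
  morphology features (foot/tangent timing).
* The landmark backends do not include a detection algorithm; real-video
  use requires an external tracker feeding the JSON-lines adapter.
* Videos are read as PNG frame directories; containerised formats (MP4,
  AVI) need prior extraction with an external tool such as ffmpeg.
* The fixed/demographic comparison on synthetic cohorts reproduces the
  *direction* of the field result (demographic information matters), not
  its magnitudes, which depend on unmodelled measurement noise.
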
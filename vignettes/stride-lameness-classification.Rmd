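---
title: "Stride-level sEMG and kinematic classification of equine lameness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stride-level sEMG and kinematic classification of equine lameness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Unilateral lameness in trotting horses shows up in two places: in the
vertical motion of the upper body (the head "nods" and the pelvis "hikes"
asymmetrically between the two halves of a stride) and in the activity of
locomotor muscles, which adapt bilaterally to unload the painful limb.
`emgait` implements a stride-level pipeline that quantifies both and asks,
for every parameter separately, how well it separates non-lame from lame
strides: vertical displacement of the poll, withers and pelvis and of the
two tubera coxae sampled at 200 Hz, bilateral surface EMG (sEMG) of seven
superficial muscles at 2000 Hz, four conditions per horse (a baseline and
an induced forelimb lameness, iFL, on one day; a baseline and an induced
hindlimb lameness, iHL, on another).

The package also contains a synthetic-trial generator with known injected
effects. Every stage of the chain can therefore be checked against ground
truth, which is how the test suite works; no animal data ships with the
package.

## Pipeline

### Gait events and strides

Hindlimb hoof impacts are detected from the hoof-height channel: contact
is the downward crossing of a threshold placed 10% of the channel range
above its minimum, debounced by 60% of the expected stride period, then
snapped forward to the sample where the hoof actually reaches the stance
plateau (2.5% of range). A crossing not followed by a real stance (at
least a tenth of a period below threshold) is discarded, so a trial
truncated mid-descent does not produce a trailing spurious event.
Externally detected events can be supplied instead; every stride-level
function accepts a precomputed event set.

A stride is the half-open interval between successive impacts of the
reference hindlimb, `[impact_k, impact_{k+1})`; a boundary sample belongs
to the later stride. Two reference conventions are used deliberately:
per-side muscles are segmented on their own side's impacts (ipsilateral
convention, for the absolute sEMG parameter), while kinematic indices and
the left-minus-right sEMG difference use left-hindlimb impacts for both
sides, so that the two sides share one temporal domain.

### Kinematic asymmetry

Upper-body displacement is high-pass filtered with a zero-phase 4th-order
Butterworth filter whose cut-off adapts to the trial: `0.5 x` the stride
frequency (reciprocal median stride duration). The factor 0.5 sits well
below both the double-oscillation frequency of trot (2 per stride) and the
1-per-stride asymmetry component, so both pass essentially unattenuated
while inter-stride drift is removed; it is a configurable default because
the convention in the source methods is not fully specified. Per stride:

* **MinDiff** = (minimum in the first half-stride) − (minimum in the
  second half-stride), halves split at the stride's time midpoint;
  **MaxDiff** analogously with maxima. Units mm; positive values mean the
  left-referenced half carries the larger value. A stride whose
  half-extrema fall on a window boundary lacks the biphasic structure and
  is dropped (and counted), not imputed.
* **Hip Hike** = (max − min) of the left tuber coxae within the left
  limb's stance (resp. swing) window minus the same amplitude for the
  right side. With only impact events available, a limb's stance window
  is approximated as own-impact to contralateral-impact. The exact
  formula used in the original kinematic literature is not restated in
  the methods this pipeline follows; the amplitude-difference form is a
  documented substitute.

An induction counts as *sufficient* when the induced-minus-baseline
difference in mean head asymmetry reaches 13 mm (MinDiff or MaxDiff poll,
forelimb case) or pelvic asymmetry reaches 5 mm (MinDiff and/or MaxDiff
pelvis, hindlimb case). The accompanying consistency clause ("standard
deviation smaller than the mean") is applied to the triggering parameter
in the *induced* condition: applied to a baseline it could never pass,
since baseline asymmetry means are near zero by construction. An
insufficient induction is flagged and warned about but does not abort the
analysis.

### sEMG parameters

Each channel is conditioned by DC-offset removal, a zero-phase 4th-order
Butterworth high-pass at 40 Hz (motion-artefact band), and full-wave
rectification. The **ARV** (average rectified value) is the mean of the
rectified signal over one stride. Then, in fixed order:

1. **Outlier removal**: within each horse x muscle x side x condition
   group, a single pass keeps ARVs inside mean ± 2 sample standard
   deviations, limits computed before any removal. Groups under 3 strides
   are kept whole with a warning.
2. **Normalization**: ARVs are expressed as percent of the maximum
   surviving baseline-stride ARV of the same horse, muscle, side and
   session (`baseline1` for iFL, `baseline2` for iHL); induced values may
   exceed 100%.
3. **sEMGabs** is the normalized ARV itself, one sample per stride per
   muscle and side (ipsilateral segmentation). **sEMGasym** is left minus
   right normalized ARV within each left-referenced stride; strides that
   lost one side to outlier removal are skipped and counted.

### Mirroring and ROC analysis

To pool horses, trials from right-side inductions are mirrored into the
left-induction frame: signed indices (kinematic, sEMGasym) are negated and
sEMGabs side labels swapped, after which sides are reported as LS (lame
side, ipsilateral to induction) and NLS. All four trials of a horse are
mirrored according to that horse's induction side — including its
baselines, which would otherwise sit in an incompatible sign frame when
pooled. Without the LS/NLS relabelling the operation is an involution,
which the tests exploit.

Strides, pooled across horses, are the classification unit. For each
parameter and induction (paired with its same-session baseline) a ROC
curve is built over all midpoint thresholds between consecutive distinct
values plus infinite sentinels. The classification direction is fixed a
priori per family — sEMGabs calls a stride lame above the threshold,
signed asymmetry parameters below it (the direction of the left-induction
sign convention) — and is never auto-selected, so below-chance AUCs are
possible and reported as-is. AUC is the trapezoidal area, numerically
identical to the Mann-Whitney probability with ties counted half (a
property the suite verifies against a brute-force all-pairs oracle). The
operating point maximizes Youden's J = sensitivity + specificity − 1,
ties broken towards higher specificity, then smaller |cut-off|. AUC bands:
excellent ≥ 0.90, good ≥ 0.80, fair ≥ 0.70, poor ≥ 0.60, otherwise
chance. A full run yields 29 rows per induction: 14 sEMGabs (7 muscles x
LS/NLS), 7 sEMGasym, 8 kinematic.

## The synthetic generator

`generate_trial()` builds, per condition and horse:

* **Upper body**: `A sin(4πf t)` (double oscillation, extrema away from
  stride boundaries) plus an asymmetry component at stride frequency `f`
  that offsets the two per-stride minima and maxima in opposite
  directions, plus slow drift (0.07 Hz) and white measurement noise.
  A positive injected asymmetry produces the lameness-typical negative
  MinDiff/MaxDiff for left-side inductions; the component sign flips for
  right-side inductions so that mirroring recovers the left frame. Poll
  and withers receive their asymmetry under iFL only, pelvis and tubera
  coxae under iHL only. Because the injected millimetre value maps
  through the waveform shape (the realized MinDiff of the noise-free
  signal is about `1/√2` times the injected value), the generator
  measures the realized asymmetry with a numeric oracle on the noise-free
  waveform and reports it in the ground truth rather than assuming it.
* **Hooves**: half-sine swing arcs over zero-height stance plateaus
  (stance duty 0.4); impact = the swing-to-stance transition, giving
  unambiguous ground-truth event times.
* **sEMG**: a stride-locked Gaussian activation burst per muscle (fixed
  muscle-specific phase, width 0.08 strides, tonic floor 0.3) multiplying
  zero-mean broadband noise band-limited to 20–450 Hz, scaled by the per
  (muscle, side, condition) amplitude factor, plus a DC offset. A
  lognormal stride-to-stride amplitude factor (CV 0.15 by default)
  emulates the burst-to-burst variability of real locomotor EMG; without
  it, stride ARVs are so stable that even a 5% amplitude change separates
  conditions almost perfectly, which real sEMG does not do. Amplitude
  factors act linearly on the expected ARV, a property the tests verify.

Stride frequency is drawn once per horse from 1.3–1.6 strides/s (typical
in-hand trot) unless fixed; the induction side is balanced across horses
and shared between a horse's two sessions, emulating a cross-over design.
Everything derives deterministically from one integer seed.

What the generator does *not* emulate: compensatory inter-limb mechanics,
3-D marker trajectories, muscle-specific waveform shapes or spectra,
activation-timing changes, fatigue, or any coupling between kinematic and
sEMG effects. Passing tests therefore demonstrate that the pipeline
recovers what was injected under controlled conditions — not that the
published discrimination figures would be reproduced on real horses.

## Numerical choices

* Zero-phase filtering doubles the effective Butterworth order; tests
  check attenuation against the squared closed-form magnitude response.
* `signal::filtfilt` applies no edge treatment, so the package centres
  each series and odd-reflects both ends (continuous value and slope)
  over three cut-off periods before filtering; start-up transients land
  in the padding. Residual transients are why input-level left-right
  mirroring checks use interior strides and a 0.05 mm tolerance, while
  parameter-level mirroring is exact by construction.
* Outlier limits use the sample (n−1) standard deviation, single pass.
* Midpoint thresholds with ±Inf sentinels reproduce conventional interior
  cut-off reporting; Youden ties prefer specificity, then small |cut-off|.
* Degenerate inputs error early and name the offending channel or group:
  missing landmarks, all-zero baseline ARV groups, sub-Nyquist cut-offs,
  fewer than 3 impacts, empty stride windows.

## Problem sizes

The test suite and acceptance script run the full chain on cohorts of 8
horses x 4 conditions x ~25 strides (about 200 strides per class per
induction) for the effect-recovery and null-calibration checks, and
smaller 1–2 horse cohorts for unit-level properties; these sizes give
Monte-Carlo error around 0.01–0.03 on an AUC, small against the 0.05–0.1
margins being asserted.

## Limitations

* The event detector is a hoof-height heuristic standing in for the
  upper-body-based classifier used in the source methods; both are valid
  event definitions, and the downstream statistics do not depend on the
  choice, but absolute impact timings may differ by a few milliseconds.
* Half-stride association for MinDiff/MaxDiff uses the time midpoint, not
  contralateral events.
* No confidence intervals or ROC-curve comparisons are computed, no
  multivariate combination of parameters, and no per-horse random-effect
  modelling: strides are pooled across horses (a stratified per-horse
  variant of the sampling is deliberately out of scope).
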
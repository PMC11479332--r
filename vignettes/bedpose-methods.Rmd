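---
title: "Detecting in-bed posture from bed-reaction forces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting in-bed posture from bed-reaction forces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedpose)
```

## The problem

Pressure injuries develop when tissue over bony prominences stays loaded for
too long; prevention hinges on regular repositioning, and monitoring
adherence requires knowing what position a person in bed is actually in.
Four load cells under the bed legs offer a fully non-contact route: the four
vertical corner forces encode the combined bed+occupant centre of mass
(CoM), and the small CoM oscillation produced by each breath carries a
directional signature that depends on how the body is rotated. `bedpose`
implements the complete analysis chain — from corner forces to a
transverse-pelvic-angle (TPA) class — together with a physics-based
simulator, because the original human recordings were collected under an
ethics approval that does not permit release. Every pipeline stage is
therefore exercised on synthetic cohorts whose generating model is documented
here.

The TPA convention is: 0° supine, negative angles left-side lying, positive
right-side lying, range (−180°, 180°]. Position classes are the coarse
triple left/supine/right (supine fixed at the open band ±22.5°) and, within
the side-lying range 22.5°–112.5° absolute, equal-width bins of 45°, 30° or
15°.

## The forward signal model

The simulator inverts the measurement equations rather than modelling
biomechanics. For load-cell spacings $w$ (width) and $l$ (length), the
measured CoM is

$$CoM_x = \frac{w}{2}\frac{LH+LF-RH-RF}{LH+LF+RH+RF},\qquad
  CoM_y = \frac{l}{2}\frac{LH+RH-LF-RF}{LH+LF+RH+RF}.$$

Given a target CoM $(x, y)$ and total load $T$, the corner forces are the
unique solution of the two moment-balance equations plus force conservation
with the diagonal difference $LH+RF-RH-LF$ set to zero:
$LH = T(1+a+b)/4$, $RH = T(1-a+b)/4$, $LF = T(1+a-b)/4$, $RF = T(1-a-b)/4$,
with $a = 2x/w$, $b = 2y/l$. Forces stay non-negative while
$|a|+|b|\le 1$; configurations outside that region are rejected.

On top of the static posture the simulator adds three components:

* **Respiration.** The CoM oscillates sinusoidally with amplitude
  `resp_amplitude` (default 4 mm, order-of-magnitude of a visible
  breath-driven weight shift) along a direction that depends on TPA through
  `resp_angle_map`. The default map is $\theta(TPA) = 72\sin(TPA/2)$
  degrees: strictly monotone over (−180°, 180°], 0° at supine, and confined
  to (−90°, 90°) so the principal-axis angle of the traced ellipse
  identifies it uniquely. No quantitative human relation between TPA and
  this orientation has been published; the map is a construction chosen so
  the three coarse classes (and the finer side bins) are separable through
  the respiration-angle feature, not a physiological claim.
* **Cardiac activity.** A force sinusoid (default 0.5 N at 1.1 Hz)
  modulates the total vertical load, giving the ballistocardiographic
  `rmsPulse` feature a non-zero target.
* **Sensor noise.** White Gaussian noise per channel (default 0.2 N).

The realized TPA inside a hold drifts as a bounded random walk clipped to
±4.5° of the target, mirroring the experimenter rule of correcting any
deviation beyond ±5°. Anthropometrics of generated cohorts are drawn to
match the reference cohort (height 174.4 ± 10.6 cm, mass 77.9 ± 19.2 kg).

The structured protocol holds 11 primary poses (0°, ±15°, ±30°, ±45°, ±60°,
±90°) for three minutes each with one-minute intermediate holds between
them; the free protocol draws 10 poses uniformly from (−180°, 180°]. The
exact ordering of the primary poses is a package choice (magnitude-ascending,
alternating sign), with supine intermediates except side-lying 90°
intermediates before the corresponding ±90° primaries so that all three
intermediate postures occur.

**What the generator does not emulate:** mattress and frame dynamics,
posture transitions (segments are cut at hold boundaries by construction),
breathing variability (amplitude and rate are constant within a
participant), movement artefacts, and any coupling between body shape and
the force distribution beyond the CoM. Passing tests on these cohorts
demonstrates that the pipeline recovers what the signal model encodes; they
are not evidence about performance on human data.

## Signal processing

**Respiration isolation.** The CoM signals are low-pass filtered with a
Chebyshev Type II design applied forward-backward (zero net phase, so
breath extrema keep their timing). The "personalized" variant estimates
each recording's dominant respiration frequency from the FFT power peak of
the detrended CoM in 0.1–0.5 Hz and places the stopband edge at 3× that
frequency, order 5, 40 dB attenuation. Those numbers come from the measured
frequency response: with stopband-edge semantics, an edge at 3× the
respiration line passes it at gain > 0.999 while a ~1.1 Hz cardiac line is
attenuated below 1%; a closer edge (e.g. 1.5×) would leave the respiration
line itself at ~0.7 gain and distort the recovered angle. A fixed 0.5 Hz
fallback specification is available where personalization is not wanted.

Numerically, the forward-backward pass is applied to the demeaned signal
with reflective padding of 100 filter lengths, and the mean is restored
afterwards: the start-up transient of an IIR filter run from zero initial
conditions scales with the signal's offset, and the respiration component
is three orders of magnitude smaller than the static CoM offset. With this
wrapper a constant input is reproduced exactly and edge error stays below
0.5% of the oscillation amplitude.

**Breath extrema.** Extrema are zero crossings of the first-order forward
difference; exact zero differences carry the previous sign so plateaus do
not spawn spurious extrema, and alternation is enforced by dropping the
less prominent member of any same-type adjacent pair. Extrema are detected
on whichever respiration axis carries more variance, and both axes are read
at those times — exact for a line-trajectory oscillation, and well-defined
when one axis is nearly flat (where its own extrema would be noise).

**Respiration angle.** For each end-exhalation maximum and the following
end-inhalation minimum,
$\arctan\left(\Delta CoM_{resp,y}/\Delta CoM_{resp,x}\right)$ in degrees,
range (−90°, 90°], with the $\Delta x = 0$ limit defined as 90°. Per-window
angles are averaged arithmetically (no circular mean): the range precludes
wrap-around.

## Features

Each pose is segmented into 45-s windows (2250 samples at 50 Hz) stepped by
15 s, giving exactly 10 windows per 3-minute hold. Twelve features per
window: mean and SD of $CoM_x$ and $CoM_y$ with y/x quotients; mean and SD
of the per-breath respiration angle; RMS of the mean-centred
respiration-band components, each normalized by the recording-level 97th
percentile of its absolute centred values, with their quotient; and the RMS
of the cardiac-band (0.8–2.5 Hz) corner forces. Two normalization decisions
deserve note: the respiration RMS is computed on *centred* signals (the raw
low-passed CoM retains the posture offset, which would swamp the
respiratory excursion), and the 97th-percentile scale is a per-axis,
per-recording quantity — normalizing each window by its own percentile
would make the RMS scale-invariant and destroy the feature. Undefined
values (no detected breath, zero denominators) are linearly interpolated
across the pose's window sequence, with nearest-value fill at the edges; a
pose with a feature undefined in every window is dropped with a warning.

## Two-phase classification

Phase One assigns the coarse label with a three-class model. Windows it
misclassifies are removed; the correctly classified left and right windows
feed Phase Two, which predicts the angular bin within the side at 45°, 30°
and 15° precision (supine has fixed width and is never subdivided; side
angles beyond 112.5° absolute are out of range). Evaluation is
leave-one-participant-out: the held-out participant's windows are split
70/30 into a fixed test set and an incremental-learning pool, stratified by
coarse label with a deterministic seeded order; at level $c \in \{0, 0.1,
0.2, 0.3\}$ the first $c/0.3$ fraction of the pool (floor rounding,
interleaved across strata so any prefix is approximately stratified) joins
the training set. The test set is identical across levels and never enters
training. The best (backend, level) configuration by mean Phase One F1
feeds Phase Two; since correctness labels exist only where a Phase One
prediction exists, the fold's Phase One model is applied in-sample to the
training participants and only its correct predictions are forwarded, while
the held-out participant contributes only its correctly classified test
windows.

Backends cover the usual feature-based roster: three gradient-boosted tree
variants — `LGB` (histogram-binned split finding, loss-guided deep trees),
`XGB` (exact greedy splits) and `GBC` (depth-3 trees, learning rate 0.1) —
all realised through xgboost's tree booster; AdaBoost (`ADA`, SAMME on
depth-limited CART trees, implemented in the package); multinomial logistic
regression (`LR`); an RBF SVM (`SVM`); and three single-hidden-layer
perceptrons of width 8/16/32 (`MLP1–3`). The published hyperparameter
tuning was not released, so library defaults with fixed seeds are used
throughout, with a per-backend override hook. Predicted labels take the
highest posterior; ties break to the lowest class index for determinism.

## Statistics

Scores are macro F1 per participant (unweighted mean of per-class F1),
then mean ± SD across participants — robust to the class imbalance that
Phase Two bins inherit from the pose protocol. Model and condition
comparisons follow the nonparametric route: Shapiro–Wilk and Levene checks,
Friedman's ANOVA across paired conditions (a fully tied matrix is reported
as statistic 0, p = 1, where the textbook formula is 0/0), and post hoc
paired Wilcoxon signed-rank tests at Bonferroni thresholds (0.05/3 ≈ 0.0167
for three comparisons, 0.025 for two). The signed-rank form is used —
despite "rank sum" naming conventions elsewhere — because the design is
paired by participant and the reported V statistic is the positive-rank
sum. The end-to-end ceiling of the cascade is the product of Phase One and
Phase Two F1 (Phase Two scores are conditional on Phase One correctness),
reported to three decimals.

## Problem sizes and test design

The test suite builds its cohorts in code: a shared n = 6, 90-s-hold
low-noise cohort for classifier mechanics; an n = 10 full-protocol cohort
for the parameter-recovery check (coarse macro F1 ≥ 0.9 at low noise); and
five n = 6 full-protocol cohorts under different master seeds for the
precision–accuracy trade-off property, which asserts that mean Phase Two F1
does not increase from 45° to 30° to 15° bins (within two SDs across
seeds). These sizes were chosen as the smallest cohorts at which the
properties are stable across seeds. Printed reference tables (cohort
anthropometrics, dataset composition, published phase scores) ship as
plain-text data and back the bookkeeping and composition identities.

## Limitations

The synthetic cohorts are a best-effort stand-in, not a replica: absolute
F1 values on them say nothing about human performance, and the respiration
orientation map is a separability construction. Sequence models over raw
windows (LSTM/CNN style) are out of scope, as are posture-transition
detection, regression on the angle itself, and real-time prompting. The
published per-test statistics (V and χ² values) depend on the unavailable
human data and are not reproduction targets; only the printed arithmetic
identities and composition values are.
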
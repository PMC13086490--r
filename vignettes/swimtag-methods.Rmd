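---
title: "Methods: from sensor streams to swimming energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sensor streams to swimming energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimtag)
```

`swimtag` chains six analysis stages: intermittent-flow respirometry, ECG
cardiography, triaxial kinematics, flow-profile modelling, calibration
transfer, and circadian mixed models, plus a seeded generator for every
input stream. This vignette explains the science in each stage, the
numerical choices behind it, and what the synthetic generators do and do not
emulate.

## Respirometry

During a measurement phase of an intermittent-flow cycle the fish depletes
oxygen in a closed volume, and the mass-specific consumption rate is

$$\dot{M}_{O_2} = \frac{\Delta O_2}{100}\cdot
  \frac{DO_{max}\, V}{BM\cdot t}\quad[\mathrm{mg\,kg^{-1}\,h^{-1}}],$$

with $\Delta O_2$ the percentage-point decline of air saturation over the
phase. The decline is not taken from endpoint readings: `compute_mo2()`
fits an ordinary least-squares line to saturation versus time and uses
$-\hat\beta_1 \times$ duration, which at 2 s sampling averages out optode
noise. The first and last 5 % of samples are trimmed because valve
transients at phase boundaries are not part of the depletion signal. Because
$\Delta O_2/t$ reduces to the slope, the estimate is independent of the
exact phase length — what matters is that the slice is a single, closed
measurement phase. A positive slope beyond a small tolerance means the
chamber was not sealed (or flushing leaked in); the record is returned as a
flagged zero rather than a negative rate.

The respirometer volume defaults to 30 l — the measurement volume of a
Brett-type swim flume's sealed section, distinct from the total recirculating
volume — and is a configuration value, as are `DO_max` and body mass.
Background (microbial) respiration is measured post-trial without a fish and
subtracted after normalising by the *fish's* body mass, which keeps the
units of both terms identical; corrected rates are clamped at zero with a
warning because a blank exceeding the animal measurement indicates a failed
blank, not negative metabolism.

Cost of transport is $COT = \dot{M}_{O_2}/(3.6\,U)$ (mg kg⁻¹ km⁻¹). The
optimal speed $U_{opt}$ is the vertex $-c_1/(2c_2)$ of a second-degree
polynomial fitted to COT versus speed; the fit is flagged invalid when the
curvature is non-positive or the vertex falls outside the tested speed
range, because then the "minimum" is an extrapolation artefact. At least
four points over three distinct speeds are required. The critical speed is
the standard prorated form $U_{crit} = U_i + (t_i/t_{ii})\,U_{ii}$. Fatigue
itself (the fish resting on the rear grid beyond 20 s) is an event supplied
by the experimenter, not detected from video. Fulton's condition factor uses
the standard $K = 100\,BM/SL^3$ (g, cm). Solid blocking is only *checked*
(fish under 10 % of the section area, strict), never corrected for.

## ECG and heart rate

Loggers record 7.5 s ECG bursts at 200 Hz every few minutes; the onboard
detection algorithm is proprietary, so `detect_r_peaks()` implements an
open Pan-Tompkins-style reduction sized for short bursts: a zero-phase
Butterworth band-pass at 5–40 Hz (the QRS energy band; zero-phase so peak
times are not shifted), first difference, squaring, and an adaptive
threshold at 0.4 × the 98th percentile of the transformed signal. Candidate
regions are collapsed to their energy maxima, a 0.2 s refractory period
(300 beats min⁻¹ — far above any salmonid heart rate) suppresses double
detections of one QRS, and each detection is snapped to the extremum of the
band-passed signal within ±40 ms, the actual R apex. All thresholds are
relative, so detection is invariant to amplitude scaling.

HR is 60 / mean(R–R) rather than a peak count divided by the window: a
7.5 s window truncates partial beats at both ends, and the mean interval is
unbiased by that truncation. The quality index mirrors logger conventions:
QI 3 when no R–R interval exists (fewer than two peaks), otherwise graded by
the coefficient of variation of the R–R intervals with breakpoints 0.05 and
0.15. These breakpoints are calibrations of this package — on the synthetic
generator they produce a QI that degrades monotonically with injected noise
— and are exposed as arguments. Filtering follows the field rule: QI 3
excluded, QI 1–2 kept but flagged for manual review (no automated
"correction" is attempted; that judgement is the analyst's).

## Kinematics

A tag measures gravity plus locomotion. `split_static_dynamic()` separates
the two with a centred running mean per axis; the default 3 s window sits
between the tail-beat period (~0.3–1 s, which must pass to the dynamic
component) and postural-change timescales (which must stay static). The
window shrinks at the trace edges so `static + dynamic` reconstructs the raw
signal exactly. Two activity metrics follow, matching the two tag families:

* **external acceleration** (logger): mean Euclidean norm
  $\overline{\sqrt{d_x^2+d_y^2+d_z^2}}$ in milli-g — "vectorial sum" read as
  the instantaneous L2 norm (per-axis RMS would be the other reading; L2 of
  the instantaneous vector is the conventional one and is what the package
  uses);
* **ODBA** (transmitter): mean L1 sum
  $\overline{|d_x|+|d_y|+|d_z|}$ converted to m s⁻² with
  $g = 9.81$ m s⁻².

By the norm inequality ODBA ≥ external acceleration × 9.81/1000 pointwise,
and both vanish iff the dynamic signal does. For a single-axis sinusoid of
amplitude $A$ the rectified mean is $2A/\pi$, which serves as the analytic
oracle in the tests (within 1 % at ≥ 10 cycles). VAR is the sample variance
of external-acceleration values within an aggregation epoch; values above
222 m*g*² (a published burst-coast/distress indicator for similarly sized
salmonids, strict comparison) flag erratic swimming.

## Flow profiles

Unsteady flow is a unidirectional sinusoid
$u(t) = \bar u + A\sin(2\pi t/P + \varphi)$ plus measurement noise; the
generated profile is the ideal set-point (PID controller dynamics are out of
scope). Fitting inverts this: for a *fixed* period the model is linear in
$(\bar u, a, b)$ via $a\sin\omega t + b\cos\omega t$, so `fit_sinusoid()`
profiles the period — the three strongest FFT bins seed golden-section
refinements of the profiled residual sum of squares and the best start wins.
This multi-start avoids the local minima that plague direct four-parameter
nonlinear fits. Amplitude is reported non-negative with phase in
$[0, 2\pi)$. A fitted amplitude below the residual noise level cannot pin
down a period and is flagged unidentifiable. On a noise-free profile the
round trip recovers (mean, amplitude, period) to four decimals; with
0.01 m s⁻¹ noise on an hour of 1 Hz data the 100 s period is recovered
within ±2 s.

## Calibration transfer

The swim-tunnel study yields four calibration lines per flow condition:
activity (external acceleration, ODBA) versus speed, and MO2 versus each
activity metric. `calibration_registry()` stores the eight published
coefficient sets as constants; `fit_line()` produces the same objects from
data (OLS on per-speed means, $R^2$ as squared Pearson correlation, the
reading consistent with fitting means as plotted).

One reconciliation deserves prominence: the acceleration–speed lines only
reproduce the published free-swimming predictions (13.04 and 13.74 milli-g
at 0.50 m s⁻¹) with speed in m s⁻¹, whereas the ODBA–speed lines only
reproduce theirs (1.33 m s⁻²) with speed expressed as a count of
0.15 m s⁻¹ protocol steps (0.50/0.15 ≈ 3.33). Each registry entry therefore
carries its own x-convention and `predict()` converts raw speed
accordingly. The steady ODBA line gives 1.07 m s⁻² against a published
1.06 — a printed-coefficient rounding gap. Similarly, chaining the steady
acceleration line into the steady MO2–acceleration line gives ≈ 226
mg kg⁻¹ h⁻¹ while ≈ 240 was reported (which instead matches the *unsteady*
MO2 line applied to the steady activity value); the package exposes both
computations and asserts neither as ground truth.

Acceleration–speed lines are calibrated over 0.30–0.75 m s⁻¹ only: at
0.90 m s⁻¹ fish switch to burst-and-glide swimming and mean acceleration
*drops*, so predictions outside the calibrated range carry an extrapolation
flag rather than silent trust.

## Circadian mixed models

Sentinel telemetry is repeated measures: epochs within fish are correlated
through stable individual differences in baseline physiology. The model is

$$y = X\beta + Zb + e,\qquad
  y \sim \mathrm{Treatment} + \mathrm{Period} + (1\mid \mathrm{fish}),$$

fitted by REML with a Gaussian random intercept per fish. The
Treatment × Period interaction is pre-tested by a maximum-likelihood
likelihood-ratio test at α = 0.05 and retained only if significant, after
which the reported model is refitted by REML; Wald tests use Satterthwaite
degrees of freedom (via `lmerTest`). A singular fit (zero intercept
variance) converges with a warning rather than failing — it simply means
the between-fish level differences are absorbed by the residual. At least
two fish and both levels of both factors are required.

Day/night labelling treats published clock ranges as inclusive hour bins:
day = hours 6–17 (06:00:00–17:59:59), night = hours 18–23 and 0–5. This is
the only convention that partitions all 24 hours without gaps; where
sources differ on the day start (06:00 vs 07:00) the package defaults to
06:00 and exposes `day_hours`. Summaries are computed from per-fish means
first, so each fish contributes one value per cell and the s.e.m. reflects
between-fish variability, matching how group summaries are reported in
telemetry studies.

## Synthetic generators: what they emulate, and what they do not

Each generator returns its ground truth, enabling closed-loop recovery
tests. Defaults encode the study conditions the package models:

* **Respirometry**: 0.30–0.90 m s⁻¹ in 0.15 steps, three 30 min cycles per
  speed (5/15/10 min), 2 s sampling; true rates ramp 213 → 307
  mg kg⁻¹ h⁻¹ (the steady-flow range for ~0.46 kg post-smolts); sensor
  noise 0.5 % saturation.
* **ECG**: a sum-of-Gaussians PQRST template — morphology is deliberately
  schematic since only peak *times* carry the contract; dropout and spike
  artifacts map to degraded QI.
* **Triaxial**: 1 g on heave plus a tail-beat sinusoid on sway whose
  rectified mean equals the calibration-line prediction at that speed, with
  tail-beat frequency increasing with speed; above 0.75 m s⁻¹ a burst-glide
  cap reproduces the published activity drop (14.30 / 15.31 milli-g).
* **Sentinel telemetry**: 10 fish, two 14-day phases (steady then
  unsteady), 10 min epochs. Cell means default to the published day/night ×
  treatment values for HR (71.10/60.50 steady, 73.20/62.50 unsteady,
  beats min⁻¹), external acceleration, VAR and ODBA; between-fish intercept
  s.d. 4 and residual s.d. 6 beats min⁻¹ for HR, scaled analogues for the
  other metrics. Feeding peaks at 09:00 and 16:00 are Gaussian bumps
  (1 h s.d.) *mean-centred over the day window*, so they produce the
  M-shaped hourly profile without shifting the day cell mean. Drawn
  intercepts are likewise centred to cohort mean zero, so the realised
  marginal cells reproduce the configured values rather than inheriting the
  sampling noise of a 10-draw mean. Consequence: the model's day–night
  contrast equals the configured cell contrast (≈ 10.65 beats min⁻¹, the
  value reported rounded as ≈ 11).
* **Transmitter stream**: detection gaps uniform on [30, 50] s, each
  detection carrying the mean ODBA since the previous one.

What the generators do **not** emulate — and therefore what passing tests do
not demonstrate about real data: optode drift and temperature sensitivity;
flush-phase mixing dynamics; ECG electrode motion artifacts with structure
(the artifacts here are white-noise spikes and dropouts); gait transitions
other than the hard burst-glide cap; tag-placement effects on the measured
axes; autocorrelated residuals in telemetry (residuals are i.i.d. Gaussian,
so the mixed-model standard errors on real data would be wider); growth
over the trial; and any fish–flow hydrodynamic interaction.

## Problem sizes and numerical choices

The test suite and acceptance script run at the study's native scales where
that is cheap (a full 4-week, 10-fish sentinel series is ~40k rows and fits
in seconds) and at reduced scales where full scale adds nothing: the
type-I-error simulation uses 100 replicates of 500 ten-minute epochs × 10
fish, and property tests use 20–50 seeded replicates. Seeds are fixed in
tests; every generator is bit-reproducible given a seed. Tolerances follow
the analytic structure: machine precision for identities (reconstruction,
COT composition), 1 % for the rectified-sine oracle at ≥ 10 cycles, 5 % for
stochastic parameter recovery at the generators' noise levels, and ±2 s for
period recovery at 0.01 m s⁻¹ flow noise.

## Known limitations

The ECG detector is tuned for clean-to-moderately-noisy bursts at salmonid
heart rates; it is not an arrhythmia-grade detector and computes no
morphology or HRV metrics. The respirometry stage does not model oxygen
solubility (DO_max is an input) nor solid-blocking velocity corrections.
The mixed model implements exactly the stated formula; in a sequential
design (steady phase first) the treatment factor is confounded with time
and growth, and the model cannot separate them. ODBA/acceleration
calibrations transfer only within the calibrated speed range and the same
tag placement; extrapolation is flagged, not prevented.
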
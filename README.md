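# swimtag

Swim-tunnel respirometry and biologging energetics for salmonids.

`swimtag` implements the full analysis chain used in heart-rate/acceleration
biologging studies of swimming fish under steady and unsteady (sinusoidally
modulated, tidal/wave-like) flow — the kind of data produced by implanted
HR/acceleration loggers and acoustic ODBA transmitters in salmon reared for
offshore aquaculture. It is aimed at fish physiologists and aquaculture
researchers who need to go from raw sensor streams to metabolic-rate
estimates and circadian activity summaries with a tested, reproducible
pipeline.

## What it computes

**Respirometry.** From intermittent-flow oxygen traces (5 min acclimation /
15 min measurement / 10 min flush cycles, 2 s sampling), the mass-specific
oxygen consumption rate

    MO2 = (dO2 / 100) · DO_max · V / (BM · t)      [mg O2 kg⁻¹ h⁻¹]

with dO2 the percentage decline of air saturation over the measurement phase
(taken from an OLS slope), DO_max the saturation concentration (mg l⁻¹), V
the respirometer volume (l), BM body mass (kg), t the phase duration (h).
Cost of transport COT = MO2 / (3.6 U), the optimal speed U_opt as the vertex
of a second-degree polynomial fitted to COT vs U, and the critical swimming
speed U_crit = U_i + (t_i / t_ii) · U_ii from the incremental-velocity test.

**Cardiography.** R-peak detection in short (7.5 s, 200 Hz) ECG bursts via a
Pan-Tompkins-style detector (zero-phase band-pass, squared derivative,
adaptive threshold, 0.2 s refractory period, apex refinement), heart rate as
60 / mean(R–R), and a 4-level quality index (QI 0 excellent … QI 3 no R–R
interval); QI 3 records are excluded and QI 1–2 flagged for review.

**Kinematics.** Static/dynamic separation of triaxial acceleration by a
centred running mean, then the two standard activity proxies: *external
acceleration* = mean Euclidean norm of the dynamic vector (milli-g), its
within-epoch variance VAR (m*g*²; values above 222 m*g*² flag burst-coast /
erratic swimming), and *ODBA* = mean L1 sum of the dynamic axes (m s⁻²).

**Flow.** Generation of steady and sinusoidal flow-speed profiles (e.g.
0.50 ± 0.05 m s⁻¹ at a 100 s period) and least-squares sinusoid fitting with
FFT period initialisation.

**Calibration transfer.** OLS calibration lines (activity vs speed, MO2 vs
activity), a registry of the eight published swim-tunnel calibrations for
post-smolt Chinook salmon, and chained prediction speed → activity → MO2
for free-swimming fish.

**Circadian mixed models.** Day/night labelling (day = hours 06–17), hourly
and day/night summaries per sentinel fish, and the repeated-measures model

    y = Xβ + Zb + e,     y ~ Treatment + Period_of_Day + (1 | fish)

fitted by REML (random intercept per fish), with an ML likelihood-ratio
pre-test for the interaction.

**Synthetic generators.** Every input stream (oxygen traces, ECG bursts,
triaxial traces, flow series, sentinel telemetry, transmitter detections)
can be generated with controllable ground truth and a seed, so the whole
pipeline is testable end to end without instrument data.

## Worked example

Simulate a respirometry session for a 0.46 kg fish, recover per-speed MO2,
and locate the optimal speed:

```r
library(swimtag)
cfg  <- respiro_config(chamber_volume = 30, do_max = 8, body_mass = 0.46)
sess <- gen_respiro_session(cfg, noise_sd = 0.5, seed = 7)
res  <- analyse_respiro_session(sess$trace, cfg)
res$summary
#>   speed_mps   mo2 mo2_sem   cot
#> 1      0.30 213.2  0.5136 197.4
#> 2      0.45 235.2  1.4956 145.2
#> 3      0.60 259.6  0.6324 120.2
#> 4      0.75 283.3  1.7173 104.9
#> 5      0.90 307.2  1.1117  94.8
```

The generator's true rates ramp from 213 to 307 mg kg⁻¹ h⁻¹; at 0.5 %
sensor noise the three-replicate means recover them to a fraction of a
percent. COT declines toward its minimum within the tested range:

```r
fit_cot_curve(res$summary$speed_mps, res$summary$cot)
#> COT curve: COT = 324.670 -521.620 U +298.289 U^2
#>   U_opt = 0.874 m/s, COT_min = 96.63 mg/kg/km

compute_ucrit(u_i = 0.75, u_ii = 0.15, t_i = 15, t_ii = 30)
#> [1] 0.825
```

Transfer the swim-tunnel calibrations to a free-swimming fish at
0.50 m s⁻¹ under unsteady flow:

```r
field_energetics_report(0.50, "unsteady")
#> Free-swimming energetics at 0.50 m/s (unsteady flow)
#>   predicted external acceleration: 13.75 milli-g
#>   predicted ODBA: 1.33 m/s^2
#>   predicted MO2 (acceleration chain): 245.2 mg/kg/h
#>   predicted MO2 (ODBA chain): 255.0 mg/kg/h
```

The predicted external acceleration and ODBA match the values observed in
free-swimming sentinel fish in tanks to within a few percent, which is what
makes implanted activity sensors usable as field metabolic-rate proxies.

A thin CLI over the same functions is installed at
`system.file("cli", "swimtag.R", package = "swimtag")` with subcommands
`simulate`, `respiro`, `hr`, `activity`, `flow`, `circadian`, `report`.

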
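---
title: "Imaging photoplethysmography of meningeal blood flow: models and methods"
author: "ippg package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging photoplethysmography of meningeal blood flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ippg)
```

## The measurement problem

Light reflected from living tissue under green illumination (530 nm) is
modulated in time by two hemodynamic processes. A *pulsatile* component,
synchronized with the heart, rides on the arterial pressure wave; its
fractional amplitude is the information carrier of imaging
photoplethysmography (iPPG). A *slowly varying* component tracks total
tissue blood volume: more blood absorbs more green light, so reflected
intensity falls as vessels dilate. This package implements the analysis of
both components for cranial-window video of the rodent meninges during
electrical stimulation of dural afferents, the preparation used to study
trigeminovascular (migraine-related) activation, together with a
fully synthetic forward model so every stage is testable without animal
data.

The two derived markers are:

* **APC** (amplitude of the pulsatile component): each 3 × 3-px region of
  interest yields a waveform AC/DC, where DC is the slowly varying
  intensity and AC the cardiac-synchronous residual. Cardiac cycles are
  delimited by ECG R-peaks; ten consecutive cycles are resampled to a
  common phase axis and averaged; APC is the max − min of this mean
  pulse, in percent.
* **OIS** (optical intrinsic signal):
  $\mathrm{OIS}_i(x,y) = \frac{I_0(x,y) - I_i(x,y)}{I_0(x,y)} \cdot 100\%$,
  with $I_0$ the first pre-stimulation frame. OIS rises with cerebral
  blood volume and doubles as a stimulation-contact quality control: a
  trial whose OIS rise during stimulation stays below 7% indicates a bad
  electrode contact.

A trial lasts 120 s: 20 s pre-stimulation, 15 s stimulation (biphasic
2 ms pulses at 10 Hz, 50 V — metadata only here), 85 s relaxation. The
full experiment applies three cumulative infusion steps (saline,
valproate, or sumatriptan; 30 min apart; three trials per step, 10 min
apart) after three baseline trials, across 32 animals in three groups.

## The synthetic forward model

`makeTissue()` builds a field of view with artery and vein paths crossing
a smoothly textured parenchyma (arteries lighter than veins, both darker
than parenchyma, 10-bit counts), class-wise fractional pulsatilities, and
two stimulation electrodes adjacent to an artery. `simulateTrial()`
renders

$$I(p,t) = \mathrm{clip}\Big(B(p)\,V(t)\,\big[1 + a(p)\,g(t)\,c(\varphi(t))\big]
  \;\oplus\; \text{motion} \;+\; \varepsilon\Big)$$

where $B$ is the baseline image, $a$ the per-pixel pulsatility,
$c(\varphi)$ a fixed cardiac template evaluated at the phase derived from
generated R-peaks, $g(t)$ the stimulation gain profile, $V(t)$ the
blood-volume intensity factor, $\oplus$ sub-pixel bilinear warping by a
low-pass-filtered random-walk offset, and $\varepsilon$ Gaussian sensor
noise clipped to the 10-bit range (clipping is counted and reported).

Numerical choices worth knowing:

* **Cardiac template.** An asymmetric raised-cosine (fast systolic rise
  over 40% of the cycle, slow decay) normalized to max − min = 1 and
  *zero mean*. Zero mean makes the temporal average of a pulsatile pixel
  equal its baseline exactly, so DC separation and OIS are unbiased by
  the heartbeat; max − min = 1 makes the injected APC of a pixel exactly
  $a \cdot g$ — the ground truth every recovery test uses.
* **Kinetics.** $g(t) = 1 + (G-1)u_a(t)$ and $V(t) = 1 - D\,u_v(t)$,
  where $u$ rises mono-exponentially during stimulation and relaxes
  mono-exponentially afterwards. Defaults: APC onset τ = 3 s, volume
  onset τ = 4 s (APC peaks before OIS, as observed), relaxation
  τ = 12 s, gain G = 1.5, volume drop D = 0.10. With trace noise around
  2% these defaults put the adaptive 2-SD return of the normalized APC
  trace near 65 s — the centre of the 40–90 s range the assay reports —
  and a stimulation-phase OIS rise near 10%, comfortably above the 7%
  contact gate.
* **Systemic traces.** ABP (72 mmHg) and HR (413 bpm) dip transiently
  during stimulation (10% and 5%) and recover with τ ≈ 4 s, much faster
  than the optical parameters. R-peaks are generated from the
  instantaneous heart rate with 3% fractional R-R jitter; the ECG is a
  train of 1 mV Gaussian deflections on a noisy baseline — detectable
  R-peaks, not realistic morphology.
* **Drug model.** The per-stage multiplier on the stimulated pulsatility
  *excess* is `timeDriftPerStep^step * drugEffect[group, step]`. The
  common drift (1.25/step) reproduces the progressive enhancement seen
  under saline; the drug rows (sumatriptan {0.8, 0.6, 0.45}, valproate
  {0.8, 0.62, 0.5}) oppose it, yielding restrained or flat responses.
  Multiplying the excess $(G-1)$ rather than $G$ keeps the gain ≥ 1 and
  models attenuation of the *evoked response*, not of baseline
  pulsatility. These magnitudes are package defaults — the assay reports
  only directions and significance patterns, not effect sizes.
* **Experiment scale.** `simulateExperiment()` generates per-trial
  parameter traces directly from the same kinetics (videos on request via
  `renderVideo = TRUE` or `simulateTrial()`); rendering 384 two-minute
  videos per cohort is neither necessary nor proportionate for
  cohort-level statistics, and the trace and pixel paths share their
  ground truth by construction.

What the generator does **not** emulate: optics (polarization, photon
transport), spatially structured illumination drift, breathing artifacts,
vessel diameter changes (volume changes are purely intensity-coded),
non-rigid local motion beyond the per-segment offsets, and any
pharmacokinetics (drug action is a phenomenological multiplier). Passing
tests on this generator therefore demonstrate correctness of the
*analysis* under the stated forward model, not robustness to every
artifact of real recordings.

## Motion compensation

The frame is tiled into 16 × 16-px segments (`makeGrid()`; edge segments
shrink). For each segment and frame, `estimateOffsets()` solves the
single-step gradient-constraint least squares

$$\min_{d} \sum_{p \in s} \big(\nabla I_{\mathrm{ref}}(p)\cdot d + (I_i(p) - I_{\mathrm{ref}}(p))\big)^2$$

with the central-difference gradient of the fixed reference frame (the
trial's first frame, the same anchor as OIS). No pyramid is used —
expected offsets are small (≤ 2 px). Segments whose 2 × 2 normal matrix
has condition number above 10³, or smallest eigenvalue below 10⁻⁶ of the
mean squared gradient, are flagged and carry zero offset, as are
estimates beyond the 8 px bound. `compensate()` reconstructs the
motion-related intensity component ($-\nabla I_{\mathrm{ref}} \cdot d$)
and subtracts it — an additive correction, not a re-warp — leaving
flagged segments untouched and keeping floating-point values.

Two deliberate choices:

* **Heartbeat suppression for estimation.** A 2% pulsatile signal on
  artery edges projects onto the image gradient and masquerades as
  ~0.3 px of spurious, cardiac-locked motion, which after subtraction
  corrupts APC. When R-peaks are available, offsets are estimated on a
  cycle-length moving-average copy of the stack (cardiac component
  nulled, slower tissue motion preserved); the correction is applied to
  the raw frames. Two-frame estimation (e.g. the constructed-shift
  oracle) is unaffected.
* **Offsets against the fixed reference, not chained**, to avoid drift
  accumulation over thousands of frames.

## PPG extraction and APC mapping

`extractWaveform()` takes the 9-pixel mean, estimates DC with a centered
moving average over one median R-R interval (rounded to an odd frame
count) — a window that nulls the cardiac component by construction — and
returns AC/DC. Near the sequence edges the window *slides* instead of
shrinking: a shrunk window spans a fraction of a cycle and leaks
heartbeat phase into DC (visible as a bias of the OIS reference frame).

`meanPulse()` resamples each of the 10 gated cycles to 50 phase points
and averages. Resampling uses a Catmull-Rom cubic kernel by default: at
desk-scale frame rates (50 fps ≈ 7.3 frames per 413-bpm cycle) linear
interpolation clips the systolic peak by 10–12%, while the cubic kernel
keeps attenuation within ~5%; `method = "linear"` restores the simpler
kernel. APC time series use a 10-cycle window sliding by one cycle
(disjoint windows available via `stepCycles`), timestamped at the window
centre. `apcMap()` computes the same quantity for every 3 × 3 tile
anchored at the image origin (residual rows/columns masked), and
`apcRoiSeries()` averages tile APC over a 27 × 27-px window — the
convention for the big-ROI response traces.

Two properties worth stating: APC is invariant to global illumination
gain (AC/DC normalization) and to the sign convention of AC
(max − min is symmetric). Sensor noise adds a *positive* bias to a
max − min statistic; with the default 2-count noise the 3 × 3-ROI APC
noise floor is roughly 0.1–0.2%, which matters when interpreting
amplitudes at or below ~0.5%.

## OIS, normalization and response metrics

OIS is computed on the DC-filtered (heartbeat-free), motion-compensated
sequence; raw-frame OIS remains available by passing any sequence to
`oisFrame()`. Pixels with $I_0 \le 1$ count are masked. The QC gate takes
the big-ROI mean OIS, subtracts the pre-stimulation mean, and passes the
trial when the stimulation-phase *peak* reaches 7% — a peak rather than a
mean, because the gate must detect any effective electrode contact.

Every per-trial parameter trace (APC, OIS, ABP, HR) is normalized to its
mean over the first 20 s, so the pre-stimulation phase averages exactly
100%. For OIS this normalization would be ill-posed (its pre-stimulation
level is ~0), so the OIS *parameter trace* is defined as 100 + OIS — the
inverted normalized DC intensity — whose excess over 100% is exactly OIS
and whose integral metrics coincide with OIS integrals.

Two integral metrics quantify each response as area between the
normalized trace and its 100% level (trapezoids on the native grid, no
resampling): the fixed stimulation-window integral over 20–35 s, and an
adaptive integral from 20 s to the first time (≥ 35 s) the trace returns
into 100% ± 2 SD of the normalized pre-stimulation samples *and stays
there for 1 s*. The hold window is an explicit choice — an instantaneous
crossing criterion stops early on noise; with zero SD the band degenerates
to an exact-equality tolerance of 10⁻⁹. Traces that never return are
integrated to the trial end and flagged truncated. Integrals are finally
divided by the mean of the animal's three baseline-trial integrals
(animals with non-positive baseline means are excluded and logged).

Big-ROI selection is automated where the assay chose windows manually:
greedy placement of six non-overlapping 27 × 27-px windows maximizing
mean APC on the map from the 10th second of stimulation, row-major
tie-breaks, with the two windows nearest the electrodes flagged
representative (ties to the higher APC). The per-trial APC/OIS traces are
the mean over those two windows.

## Statistical design

All inference is rank-based, mirroring the assay's plan:
Kolmogorov–Smirnov normality screening (recorded, never branching — the
path is nonparametric regardless), two-sided Wilcoxon signed-rank for the
within-trial 10 s vs 30 s contrast, Friedman across repeated stages per
group, Kruskal–Wallis across groups per stage, and Bonferroni-corrected
pairwise post-hoc contrasts (signed-rank within groups, Mann–Whitney
between groups; family = all pairs of the omnibus test) gated on the
omnibus rejection at α = 0.05. The signed-rank test uses the exact null
distribution for n ≤ 25 (zero- and tie-free), the continuity-corrected
normal approximation otherwise. The value entering Friedman/KW for one
animal and stage is the mean baseline-normalized adaptive integral over
the three trials at that stage.

One structural caveat: across stages, the baseline's own normalized value
is identically 1 for every animal (the same trials define the
normalizer), so the stage-layout Friedman test is conservative under the
null. Calibration checks therefore run Friedman on the exchangeable
layout — the three stationary baseline trials per animal — where measured
type-I error sits at the nominal level; the stage layout remains the
reporting path.

## Problem sizes and limitations

Tests and the acceptance script run at desk scale: 188 × 120 px at
50 fps (the full 752 × 480 at 100 fps is a configuration away), trials of
6–36 s where a property does not need the full 120 s timeline, cohorts of
8 animals per group for calibration loops (100–200 replicates) and the
printed design (11/10/11) for pattern-level checks. 50 fps is near the
sampling limit for a 413-bpm heart (Nyquist ratio ≈ 3.6); the cubic
resampling keeps APC recovery within ~5% there, and accuracy improves to
~1% at 100 fps.

Known limitations: the additive first-order motion correction cannot
remove large or rotational motion; the APC noise floor biases very small
amplitudes upward; OIS and APC share the relaxation time constant in the
generator (real tissue may decouple them); and the statistical power
claims hold under the generator's lognormal animal/trial variability
(10%/5%), not under arbitrary real-world heterogeneity.
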
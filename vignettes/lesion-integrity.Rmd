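---
title: "Assessing linear ablation lesions from MAPs and contact force"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing linear ablation lesions from MAPs and contact force}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapgap)
```

## The problem

Linear radiofrequency ablation lesions — for example across the left-atrial
mitral isthmus — fail when they contain *conduction gaps*: islands of
electrically viable myocardium inside the intended line that keep conducting
and can sustain macro-reentrant tachycardia. A monophasic action potential
(MAP) catheter pressed onto tissue records the local transmembrane action
potential time course when, and only when, two conditions hold: the tissue
under the tip is viable, and the contact force (CF) is sufficient. That
coupling is the basis of the assessment implemented here: if a site inside a
lesion line still yields MAPs, it is a gap; if it yields none *despite
proven contact*, it is non-conductive.

`mapgap` implements this assessment as a reusable pipeline from raw
co-recorded signals — the bipolar MAP electrogram, a reference ECG, and the
wavelength shift of a fiber Bragg grating (FBG) force sensor — to a per-site
label: `conductive`, `non_conductive`, `gap`, or `indeterminate`.

## The decision model

Every surveyed site is assessed once before and once after ablation. A beat
carries a MAP when the deflection satisfies the acquisition criteria:
amplitude strictly greater than 2 mV (peak relative to the pre-upstroke
baseline) and duration of at least 100 ms (inclusive). A site counts as
*MAP-positive* only after a run of 4 consecutive MAP waveforms with similar
characteristics, which suppresses spurious detections from intermittent
contact during cardiac motion; the contact force is read at the **last**
beat of that first qualifying run.

Per beat, three repolarization metrics are measured against the earliest
recorded ventricular activation (QRS onset on the reference ECG):

* **AT** — earliest activation to local activation (maximum upstroke
  velocity of the MAP);
* **EOR** — earliest activation to local end of repolarization (first
  post-peak recovery of 90% of the amplitude toward baseline, APD90-style);
* **MAPDUR** = EOR − AT, identically.

Post-ablation classification is a four-way total rule:

| MAP present | On lesion line | Force vs reference | Label |
|---|---|---|---|
| yes | yes | — | `gap` |
| yes | no  | — | `conductive` |
| no  | —   | exceeded (strict) | `non_conductive` |
| no  | —   | not exceeded | `indeterminate` |

The force comparator is the site-matched pre-ablation CF at detection when
one exists, and otherwise the cohort reference — on viable epicardial
ventricular septum, MAPs appear at a mean CF of 7.6 ± 4.4 g
(`septalReference()`). The `indeterminate` label is this package's own
safety addition: a silent site probed only below the reference force has
not demonstrated non-conductivity, merely insufficient contact, and calling
it non-conductive would overstate lesion completeness. For the same reason
a tie with the reference falls to `indeterminate` rather than
`non_conductive`.

## Force calibration

The FBG sensor reports a wavelength shift (nm) that is linear in applied
force over the working range. `fitCalibration()` fits
`force = slope · shift + intercept` by ordinary least squares per fiber,
with a free intercept (the bench protocol does not force the line through
the origin; the intercept is recorded). Calibration is per-fiber and
mandatory: `applyCalibration()` refuses a curve whose fiber identity does
not match the recording. Calibrated forces are clipped at 0 g — contact
force is non-negative by definition — and clipping is reported.

## Detection: numerical choices

* **Filtering.** The acquisition band is 0.1–120 Hz. It is realized as a
  cascade of Butterworth sections applied zero-phase (forward–backward), so
  fiducial timing is not skewed. Two numerical points: a directly designed
  band-pass with a lower edge at 1/5000 of Nyquist is fragile, so high-pass
  and low-pass are cascaded; and forward–backward filtering squares the
  magnitude response, so the low-pass is order 3 (a squared second-order
  section would already sag ~6% at 60 Hz), while the 0.1 Hz high-pass stays
  order 2 for stability.
* **QRS references.** R peaks are local maxima above half the global
  maximum with a 300 ms refractory rule (larger peak wins). This is
  deliberately simple; it is accurate to well under 10 ms on the kinds of
  high-SNR reference ECGs this pipeline consumes.
* **Beat windows** span from 150 ms before each R peak to 150 ms before the
  next (median RR for the last beat). The window cores partition the trace
  interior, so every sample is assessed exactly once.
* **Baseline** is the median of the pre-upstroke window segment, robust to
  the residual wander the 0.1 Hz high-pass leaves behind.
* **Local activation** is the time of the maximum 5-point-smoothed first
  difference at or after the QRS.
* **Boundary behavior** is pinned by unit tests: amplitude exactly 2.0 mV
  is *not* a MAP (strict), duration exactly 100 ms *is* (inclusive). The
  duration comparison carries a 1e-9 ms guard so floating-point
  cancellation cannot flip a beat sitting exactly on the boundary.
* **Similarity** for the 4-beat rule is not defined operationally in the
  source protocol; here two beats are similar when their relative
  difference — in both amplitude and MAPDUR, relative to the larger value —
  is at most 15% (`similarityTolerance`). If several runs qualify, the
  earliest beat index wins.
* Whether the amplitude criterion is peak-to-baseline or peak-to-peak is
  likewise not stated; the default is peak-to-baseline, with
  `amplitudeMode = "peak_to_peak"` exposed.

## The synthetic generator

No raw recordings were deposited with the study this package operationalises,
so the generator is a first-class, tested module that encodes the
statistical structure the analysis assumes:

* **Elicitation is a hard per-site force threshold** (a step, not a
  sigmoid): the protocol treats MAP appearance during a slow force ramp as
  a threshold event, and that is what the generator reproduces. A beat
  carries a MAP iff the site is viable and the instantaneous CF at the MAP
  onset reaches the site threshold.
* **Thresholds** across viable sites follow a normal with mean 7.6 g and SD
  4.4 g, truncated at 0.5 g (non-physical near-zero forces excluded).
  Plain truncation would shift the realized mean to ~8.1 g and shrink the
  SD, so the underlying location/scale are solved numerically such that the
  *truncated* distribution has exactly the configured moments
  (moment-matched truncation). Ablated sites never produce a MAP at any
  force.
* **Waveforms.** The MAP template is piecewise — 2 ms linear upstroke, flat
  plateau, exponential repolarization tail — parameterized by amplitude and
  duration, with the plateau/tail split chosen so the APD90-style duration
  equals the configured value. This matches the morphological criteria the
  detector tests without inventing further physiology. Per-site amplitude
  (3–6 mV) and duration (150–250 ms) are uniform draws; the source protocol
  reports only the 2 mV / 100 ms detection floor, so these ranges are
  plausible-but-arbitrary and flagged as such in the configuration docs.
* **Negatives are realistic, not silent:** sub-threshold and ablated beats
  carry a blunt far-field deflection (0.3 mV, below the 2 mV criterion)
  plus noise.
* **Disturbances.** Additive Gaussian noise (0.05 mV) on the electrogram
  channels; sinusoidal respiratory wander (0.2 mV on the MAP channel,
  0.3 g on the applied force, 4 s period) suppressed when the breath-hold
  flag is set — modelling the momentary 10–20 s breath holds used during
  in-situ measurements. A sinusoid is the minimal stand-in for lung motion.
* **Sensor model.** The sensor channel encodes the applied force through
  the inverse of a canonical fiber calibration (5 g/nm, intercept 0) plus
  wavelength noise (0.01 nm), so the calibration stage is exercised
  end-to-end.
* **Defaults** of 1000 Hz sampling (resolves the 2 ms upstroke) and 80 bpm
  are unspecified upstream and chosen once as realistic values.
* **Determinism.** Identical seed + configuration give bit-identical
  traces; surveys derive per-site child seeds from the master seed.

The **operator protocol** is modelled explicitly: force ramps at 0.25 g per
beat and holds at the first beat-level crossing of the target (plus the
respiratory force amplitude, so wander cannot push the held force back
under threshold). Post-ablation, silent sites are probed up to
`max(15 g, site threshold + 2 g)`, mirroring the practice of pushing the
force beyond the site's own pre-ablation requirement before declaring it
silent.

What the generator does **not** emulate — and hence what passing tests do
not show about recorded data: no membrane-kinetics electrophysiology, no
ectopy or arrhythmia, no electrode drift or motion artifacts beyond the
sinusoidal wander, no far-field morphology changes near lesion edges, no
temperature effects on the fiber, and QRS morphology far cleaner than a
clinical ECG. Detector performance on real recordings must be established
separately.

## Worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 42)
pat <- lesionPattern(3, 3, patternSites = c("B1", "B2", "B3"),
                     gapSites = "B2")
sv <- generateSurvey(pat, cfg)
res <- analyzeSurvey(sv)
res$report
```

The report counts sites by label separately for in-pattern and
out-of-pattern sites — whether viable tissue *next to* a line should enter
gap statistics is a reporting choice, so the report does not conflate the
two — and lists the recovered gap sites (`B2` above).

## Validation strategy and problem sizes

The test suite validates every stage against an independent oracle rather
than against itself: closed-form normal equations for the calibration fit,
an analytic frequency response for the filter, brute-force ramp-crossing
and nearest-time matching for elicitation and QRS detection, an exhaustive
scan for the 4-beat rule, exhaustive enumeration of the 8-way classification
truth table, and planted ground truth for end-to-end gap recovery (0–3 gaps
per pattern, 20 replicates each, on a 2×3 grid). The distribution-recovery
experiment processes 20 replicate pre-ablation surveys of 200 viable sites
through the full pipeline and checks the pooled CF-at-detection mean and SD
against the configured 7.6/4.4 g; pooling across replicates is used because
a single 200-site survey estimates the mean with a standard error of
~0.31 g, so per-replicate bands at 2 SE would fail by sampling noise alone
in about one replicate in twenty even for an exact pipeline.

## Known limitations

* The EOR definition (90% recovery) is one of several defensible
  operationalisations of "end of repolarization"; it is configurable
  (`repolarizationFraction`) and all reported MAPDURs depend on it.
* The measured CF at detection is biased a fraction of a gram above the
  true site threshold (ramp quantization plus the respiratory guard in the
  hold level) — visible in the recovery experiment as a mean a few tenths
  of a gram above 7.6 g.
* The classifier trusts its inputs' pattern membership; mis-registered
  catheter positions translate directly into mislabels.
* Calibration assumes linearity over the working force range and does not
  compensate temperature.
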
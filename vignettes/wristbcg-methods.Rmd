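---
title: "Methods: wrist BCG timing and amplitude estimation with a calibrated synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wrist BCG timing and amplitude estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristbcg)
```

## The measurement problem

A wrist-worn accelerometer records a ballistocardiogram (BCG): the recoil of
the body, transmitted to the limb, as blood is ejected from the left ventricle
each beat. The systolic I-J-K complex of the wrist BCG is a usable proximal
timing marker of aortic valve opening (AVO). Combining it with a distal marker
of pulse-wave arrival — here the foot of the thumb photoplethysmogram (PPG) —
gives the pulse transit time (PTT), a correlate of arterial stiffness and
blood pressure, from sensors on a single limb. During ergometer exercise the
signal is buried under pedalling artifact and broadband sensor noise, so the
measurement chain is:

1. **Synchronization** (`resample_common`): all channels (accelerometer
   900 Hz, tonometry 200 Hz, PPG/arterial line 125 Hz, ECG 500 Hz, LVOT
   Doppler) are mapped to a common clock using shared timing-signal events
   (mean offset; least-squares drift when three or more events exist) and
   resampled to 500 Hz.
2. **Gating and ensemble averaging** (`detect_systolic_peaks`,
   `segment_beats`, `ensemble_average`): the radial tonometry systolic peak
   gates ±400 ms beat segments (401 samples at 500 Hz, peak at sample 201);
   segments with outlying RMS (median + 3 MAD) are rejected; the rest are
   averaged per condition.
3. **Decomposition** (`eemd`, `select_systolic_imf`): the ensemble average is
   decomposed by ensemble empirical mode decomposition; the intrinsic mode
   functions (IMFs) whose Welch-spectral energy concentrates in 10–30 Hz form
   the "filtered BCG" carrying the systolic complex.
4. **Features** (`detect_avo_onset`, `foot_intersecting_tangents`,
   `compute_ptt`, `bcg_amplitude`, `bp_metrics`, `heart_rate`, `doppler_vti`,
   `stroke_volume`): the systolic-complex onset (AVO marker) is the peak
   immediately preceding the first major negative deflection of the filtered
   BCG; the PPG foot is located by intersecting tangents; PTT is their
   difference; amplitude is the topographic prominence of the largest peak
   within 120 ms of onset; SBP/DBP are per-beat extremes of the arterial
   line, MAP its per-beat time average; stroke volume is the Doppler
   velocity-time integral times the LVOT cross-sectional area.
5. **Statistics** (`wilcoxon_signed_rank`, `pearson`,
   `compare_dependent_correlations`, `robust_mahalanobis_outliers`,
   `zscore`, `run_pipeline`): paired two-sided signed-rank posture
   comparisons per load (α = 0.05, no multiplicity correction by default, a
   Holm-style correction can be applied downstream), PTT–SBP and PTT–HR
   Pearson correlations per posture and pooled, and the stroke-volume versus
   amplitude correlation with and without robust outlier exclusion.

Because no public recordings exist for this protocol, the package ships a
synthetic cohort generator with beat-level ground truth; every stage above is
validated by parameter recovery against it.

## The synthetic cohort and what it emulates

`cohort_spec()` defaults describe the study conditions: 25 participants, two
postures (supine, semirecumbent at 30°) by four ergometer loads (0, 50, 100,
150 W), with at least two minutes of steady-state recording per condition and
60 RPM cadence. Per-condition population means and SDs of HR, SBP, DBP, PTT
and systolic amplitude come from the published summary table
(`reference_conditions()`); participant-level random effects are drawn from
those distributions, truncated to physiological invariants (0 < DBP < SBP,
0 < PTT < beat interval, positive amplitude).

Per beat, the generator enforces the systolic timing chain by construction:
the R peak at `r_time`, AVO at `r_time + PEP`, the radial (tonometry/ABP)
pulse foot at `AVO + 50 ms`, the radial systolic peak 150 ms after its foot,
and the thumb-PPG foot at `AVO + PTT`. This places the BCG complex
100–200 ms before the radial systolic peak and the PPG foot shortly after it,
so both PTT endpoints fall inside the ±400 ms gating window — the geometry
the real recordings show. The identity `PAT = PEP + PTT` therefore holds
exactly for every generated beat. PEP is not tabulated in the study; the
default falls linearly from 90 ms at rest to 60 ms at 150 W, and only the PAT
identity — not PEP's value — is ever tested. Stroke volume is likewise not
tabulated; the default rises from 70 mL at rest to a 110 mL plateau from
100 W (matching the reported plateau behavior) and is used only for
round-trip recovery tests, not for comparisons against published values.

Channel models:

* **BCG** (`synth_bcg`): each beat contributes a Gabor atom (20 Hz carrier,
  25 ms Gaussian envelope — "tightly localized in time" in the 10–30 Hz
  band), a 30% diastolic echo 250 ms later, cadence-harmonic motion artifact
  (1–10 Hz, amplitude zero at 0 W growing linearly to 5× the burst amplitude
  at 150 W — strong enough to stress the decomposition), and white sensor
  noise at 220 µg/√Hz. Two conventions define the ground truth: the atom's
  *first positive local maximum* sits exactly at `AVO + 10 ms` (the extremum
  location is solved numerically, since the Gaussian envelope shifts the
  product's extrema off the carrier peaks by several ms), and the main peak's
  topographic prominence equals the condition amplitude.
* **Pressure channels** (`synth_pressure_channels`): the radial pulse rises
  from its foot with a quarter-sine upstroke — maximum slope at the foot, so
  the intersecting-tangents method recovers the radial foot exactly — and
  relaxes exponentially to the next foot; ABP spans exactly [DBP, SBP] per
  beat. Tonometry shares the waveform timing but its upstroke is a
  *truncated* quarter sine, giving a corner-like systolic peak: with a flat
  sine top, argmax gating wanders several ms under tonometer noise and
  smears the ensemble; a corner peak is locatable to about one sample. The
  PPG uses a smoother raised-cosine upstroke (55 ms) from the true pulse
  foot.
* **Doppler** (`synth_doppler`): a half-sine ejection velocity profile from
  AVO over the ejection duration, with peak velocity solved so that
  VTI × LVOT area equals the true stroke volume.
* **ECG**: a stylized PQRST with a dominant, locatable R peak (no further
  morphological realism is attempted).

Per-channel clock offsets (±0.25 s) and shared timing events every 10 s
exercise the synchronization stage; all channels are deterministic given the
cohort seed.

### Unit convention for the accelerometer

The published amplitude scale ("µG") and the published sensor noise floor
(220 µg/√Hz) cannot both be micro-g: white noise at that density carries
≈ 980 µg RMS in the 10–30 Hz band, and even a 140-beat ensemble average
leaves ≈ 85 µg — several times a 29.5 µg amplitude, which would have made
the published extraction impossible. Wrist-acceleration BCG amplitudes in the
broader literature are in the mG range, so this package generates the
accelerometer channel in **mG** and reads the published amplitude numbers on
that scale, while the noise floor keeps its datasheet value
(0.22 mG/√Hz = 220 µg/√Hz). All published numerals are then reproduced as
printed, on a physically consistent signal-to-noise ratio.

### Built-in estimator offsets and why they cancel

Two small systematic offsets are inherent to the conventions: the detected
onset is the burst's first positive peak, 10 ms *after* AVO; and the
intersecting-tangents foot of a raised-cosine upstroke of duration $T$ sits
$T(1/2 - 1/\pi)$ *after* the true foot. With the default 55 ms PPG upstroke
the tangent delay is ≈ 10 ms, so the two offsets cancel and the end-to-end
PTT estimator is unbiased by construction — mirroring how fixed detector
latencies cancel in differential timing measurements on real hardware.

## Decomposition details

`emd()` uses classical sifting with cubic-spline envelopes through the
extrema, mirror-extending the two outermost extrema about the record ends
(envelope end effects otherwise dominate short segments). A mode is accepted
by the S-number rule (extremum and zero-crossing counts within one of each
other on two consecutive sifts) or after 50 sifts; decomposition stops on a
monotone residue or fewer than 8 extrema. Plain EMD is exactly additive, and
the test suite asserts reconstruction to < 1e−10 relative error.

`eemd()` adds white noise at 0.2 × signal SD over 200 ensembles (both
config-exposed; values follow common practice — the study reports neither).
Mode counts are harmonized to the modal count across realizations: shorter
decompositions are zero-padded, extra trailing modes fold into the residue.
Reconstruction then holds within 3σ/√(n\_ensembles).

Noise-assisted averaging can split one transient across two adjacent modes.
The selection rule is therefore made explicit and two-tiered: the *systolic
IMF* is the single mode maximizing the 10–30 Hz Welch band fraction
(ties to the lower index; a fixed index can be forced to replicate a
visually chosen mode), and the *filtered BCG* is the sum of all modes whose
band fraction reaches 0.5. Onset and amplitude are measured on that sum;
with a clean decomposition it coincides with the single systolic IMF.

## Numerical choices and degenerate inputs

* Tonometry peak detection: candidate maxima must reach 40% of the local
  beat amplitude (rolling median of block-maximal prominences over 2 s
  blocks) with a refractory period of one minimum beat interval at
  220 bpm; prominence ties break to the earlier sample. Fewer than three
  surviving peaks is a segmentation failure.
* "Major negative deflection" for onset detection is quantified as ≥ 50%
  of the window's largest negative prominence (config-exposed), and the
  preceding maximum must carry at least 5% positive prominence so residual
  decomposition wiggles on a downslope are not taken as the onset peak.
* The tangent slope uses a 5-point quadratic Savitzky–Golay first
  derivative, making foot placement reproducible at 500 Hz.
* MAP integrates the full inclusive peak-to-peak span (trapezoid), the
  arterial-line monitor convention, rather than DBP + PP/3.
* Stroke volume uses the LVOT *area* formula; the diameter-product variant
  that some reports quote is available as a compatibility flag
  (`use_area = FALSE`).
* Robust outlier exclusion uses a seeded MCD fit (subset fraction 0.75)
  with the standard reweighting step and normal-model consistency factor;
  distances are compared to the χ²(df = 2) quantile at 1 − α.
* The exact signed-rank branch enumerates all 2^m sign assignments for
  m ≤ 12 non-zero differences (midranks for ties, zeros dropped); beyond
  that a tie-corrected normal approximation with continuity correction is
  used. All differences zero returns p = 1 with a degenerate flag.
* Z-scores use the sample-SD denominator (as `scale()` does); the choice is
  immaterial for the correlations computed from them.
* The common rate is 500 Hz: the study does not state one, and 500 Hz keeps
  the 10–40 Hz BCG band far below Nyquist while matching the highest native
  rate (ECG). Upsampled channels are cubic-spline interpolated; downsampled
  ones are first zero-phase low-pass filtered (6th-order Butterworth at 90%
  of the target Nyquist). Edges beyond a channel's support are dropped.

## What the tests do and do not show

The acceptance checks run the full pipeline on cohorts whose ground truth is
drawn from the published per-condition distributions and ask for cohort-mean
recovery: PTT within 8 ms (supine rest, semirecumbent rest, supine 150 W with
full motion artifact), amplitude within 20%, SBP/DBP within 0.5 mmHg on
noiseless pressure data, HR within 2 bpm, and the noise floor within 10%.
The suite and the acceptance script use 25 participants at 30 s per
condition: the beat-level measurement is steady-state, so duration mainly
sets the ensemble size (~35 beats at rest), and 30 s keeps the full
three-condition recovery run to a few minutes. Note that with 25 participants
the cohort-mean of the *drawn* ground truth already moves by ±5 ms (PTT) or
±2.4 bpm (HR) SE around the population value, so these tolerances are tested
jointly against sampling and measurement error.

Passing these tests shows the chain is self-consistent and unbiased under
the generator's assumptions. Real wrist recordings differ in ways the
generator deliberately does not model: BCG morphology varies strongly
between individuals (the atom here is one fixed shape), respiration and
baroreflex modulate beat-to-beat timing, motion artifact is broadband and
non-stationary rather than a clean cadence comb, sensors lose contact, and
the PPG foot shape changes with vasomotor tone. Recovery on synthetic data
is therefore necessary, not sufficient, evidence for field performance.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_participants = 2, duration_s = 30, seed = 42)
cohort <- generate_cohort(spec, conditions = c(1, 5))   # both postures, 0 W
report <- run_pipeline(cohort, seed = 1)
report$condition_summary[, c("posture", "load_w", "ptt_ms_mean", "amp_mg_mean")]
```

## Known limitations

* EEMD on 401-sample ensemble averages is the computational bottleneck
  (~1–2 s per condition at 200 ensembles); long cohorts should be run with
  the per-condition loop parallelized externally.
* The aligned-rank-transform factorial analysis reported alongside the
  original paired tests is out of scope; only the paired posture tests,
  correlations and outlier-screened correlation are reproduced.
* Ensemble averaging assumes local stationarity; dynamically varying heart
  rate within a condition violates it, and the generator's modest interval
  jitter (CV 0.03) does not probe that regime.
* `read_cohort()` restores recordings from disk for reprocessing but not the
  realized generator parameters; ground truth travels in the annotation
  table.
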
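---
title: "Methods: automated action-potential analysis for cardiac microtissue optical mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated action-potential analysis for cardiac microtissue optical mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardiomapr)
```

# The measurement problem

Optical mapping of 3D human cardiac microtissues records a voltage-sensitive
dye (di-4-ANEPPS) with a fast EMCCD camera — here 979 frames/s over a 64 × 64
pixel field at 18.7 µm/pixel, so a 1.2 × 1.2 mm view that typically holds
four microtissues. The tissues are field-paced at a 2 s cycle length (0.5 Hz)
and recorded for 8–10 s. The raw product is a movie stack; the scientific
product is, per microtissue and per beat, a panel of eight pro-arrhythmia
metrics:

* **excitability** — % of delivered stimuli that evoke a captured AP;
* **stimulation delay** — pulse onset to the AP upstroke (max dF/dt), ms;
* **rise time** — 10–90% upstroke time, ms;
* **APD30 / APD50 / APD80** — duration from the upstroke to 30/50/80%
  repolarization of the beat amplitude, ms;
* **APD_MxR** — duration to the end of rapid (phase-3) repolarization,
  located at the maximum of the second time-derivative of the trace, ms;
* **APD_tri** — triangulation, defined exactly as APD_MxR − APD50, ms;
* **EAD flag** — whether an early afterdepolarization interrupts
  repolarization.

`cardiomapr` implements the full chain — movie → active pixels → microtissue
regions → averaged ΔF/F traces → per-beat metrics → study-level statistics —
plus a ground-truthed synthetic-data generator, because no raw recordings are
publicly deposited for this platform. Every pipeline stage is a
data-frame-in / tibble-out function, so analyses compose with the pipe.

# Segmentation by pacing-band periodicity

Pixels carrying paced APs are periodic at the pacing frequency. For each
pixel, `pixel_activity()` removes a linear trend, takes the FFT, and scores
the fraction of one-sided spectral power falling in narrow bands around the
pacing fundamental and its first three harmonics (±1 frequency bin each),
excluding the DC bin. APs are strongly non-sinusoidal, so the harmonics carry
much of the power; a pure in-band signal scores ≈ 1 and white noise scores
the flat-spectrum band fraction (≈ 12 bins / (T/2)). Scores are bounded in
[0, 1] regardless of gain, which makes thresholds transferable across
recordings.

`segment_rois()` binarizes the score map with Otsu's threshold (a fixed
threshold is available for strict reproducibility), labels 8-connected
components with a deterministic raster-order BFS, fills single-pixel holes,
and discards components not **strictly larger** than `min_pixels = 60` — the
platform's published inclusion rule (a typical microtissue covers ~170
pixels). Components touching the border are retained; the rule is surfaced in
the run config. `extract_traces()` then averages raw counts over each
region's pixels, negates if the dye polarity is inverted (di-4-ANEPPS
emission falls on depolarization under common filter sets), and normalizes to
ΔF/F with F0 = the mean of the lowest-quartile samples of the averaged trace.
The lowest-quartile definition is robust to the pacing duty cycle: at 0.5 Hz
pacing the trace spends well over a quarter of its time at diastole.

# Per-beat metrics

`detect_beats()` assigns one analysis window per stimulus (pulse onset to
next onset). A beat is **captured** when a positive deflection whose
amplitude is ≥ 50% of the median candidate-beat amplitude has its maximum
upstroke velocity within 300 ms of the pulse. Both constants are exposed
(`capture_amp_frac`, `capture_window_ms`); the published analysis never
defines "captured", so these are package defaults, not claims. Spontaneous
beats not locked to a stimulus are ignored.

All durations reference `t_act`, the time of the maximum smoothed first
derivative, and all repolarization levels reference the per-beat amplitude
above the diastolic baseline (median of the last 10% of the preceding
window): dye signals are uncalibrated, so absolute levels carry no meaning.
Level crossings are linearly interpolated between samples, which is what
makes sub-sample accuracy possible at 979 Hz (observed errors ~0.15 ms
against a 10 kHz analytic oracle).

Derivatives come from a zero-phase Savitzky–Golay polynomial filter
(`signal::sgolayfilt`, order 3): 5 ms window for the first derivative, 11 ms
for the second. Raw second differences of a sampled optical trace are
noise-dominated; the symmetric filter preserves peak locations (it is exact
on cubics), so the curvature maximum that defines APD_MxR moves by less than
two sample periods. The APD_MxR search runs from the APD50 crossing to the completion of
repolarization (the first smoothed crossing below baseline + 2% of the
beat amplitude), avoiding both the filter's edge transient and the flat
diastolic tail, whose smoothed-curvature noise would otherwise outscore
the phase-3 curvature peak on realistic traces.

The **EAD detector** looks between the primary AP peak and 90%
repolarization for a smoothed-derivative sign change (repolarization
reversing into depolarization) followed by a re-depolarization of at least
5% of the beat amplitude that persists ≥ 20 ms. The anchor is the *first*
major local maximum, not the global maximum — a large EAD riding the plateau
can exceed the AP peak. The published work reports EAD incidence but no
detector criteria; ours is a documented surrogate with measured operating
characteristics (sensitivity 1.0 for bumps ≥ 10% of amplitude on noiseless
beats; false-positive rate ≤ 5% at 2% amplitude noise). EAD-bearing beats
keep their APD values and feed the summaries, since EADs dramatically
prolong APD and that prolongation is part of the signal.

# The synthetic-data generator

The generator exists to give the pipeline inputs with known truth; its
defaults are the study conditions, not tuning knobs.

**Waveforms** (`waveform_params()`, `make_ap_waveform()`) are the product of
two logistic sigmoids (upstroke time constant `tau_up`, phase-3 midpoint
`t_repol` and steepness `tau_repol`) and an exponential plateau decay, with
an optional Gaussian EAD bump gated to the repolarization phase. This family
was chosen because APD30/50/80, APD_MxR and triangulation are independently
steerable. Ground truth is computed by brute-force definition scan on a
≥10 kHz grid of the *analytic* waveform — fully independent of the
measurement path — and refining that grid 10× moves no truth value by more
than 0.1 ms.

**Movies** (`scene_spec()`, `render_movie()`) place non-overlapping circular
tissues in the 64 × 64 field; each in-tissue pixel carries
`baseline ± ΔF/F·baseline·waveform-train` (sign per dye polarity, inverted
by default) plus i.i.d. Gaussian noise. A 7.4 px radius gives ~170 pixels,
the platform's typical footprint. What the renderer deliberately does *not*
model: photon (Poisson/EMCCD-gain) statistics, photobleaching, motion,
partial-volume edge pixels, conduction delays within a tissue, and 3D light
scattering. Passing segmentation tests therefore demonstrates correctness of
the spectral-detection logic under additive noise, not robustness to every
optical artifact of a real rig.

**Hierarchical APD sets** (`variance_spec()`,
`sample_hierarchical_apds()`) draw
`APD(b,m,t,k) = grand mean + B_b + M_bm + T_bmt + ε_bmtk` with independent
normal effects. Defaults are the lactate-purified platform's published level
SDs — beat 6.4, tissue 36.1, mold 31.8, batch 19.3 ms around a 259 ms grand
mean — at 4 batches × 3 molds × 35 tissues × 5 beats.

**The ionic model** (`ionic_scales()`, `simulate_ionic_ap()`) is the
Bueno-Orovio–Cherry–Fenton minimal ventricular model (epicardial parameter
set), integrated by fixed-step forward Euler (0.02–0.025 ms) in compiled
code and paced to a period-1 steady state (beat-to-beat APD80 change
< 0.5 ms). The source study never names its simulation model, so only
directional claims are made here. The model has three currents — fast
inward, slow outward, slow inward — and no separate transient-outward
current; we therefore split the slow outward current at its threshold gate:
the supra-threshold phase-3 component is scaled by `g_kr_scale` (I_Kr
surrogate), the sub-threshold component by `g_to_scale` (I_to/I_K1
surrogate), and the slow inward current by `g_cal_scale` (I_CaL surrogate).
Under this mapping, graded I_Kr-surrogate block prolongs APD80 and steepens
triangulation monotonically; I_to-surrogate block barely moves either; and
I_CaL augmentation prolongs APD with flat triangulation at moderate doses.

# Study-level statistics

**Variance decomposition** (`variance_components()`) follows the platform's
sequential-SD scheme rather than a REML mixed model, because that is what
the replicate analysis reports: per-tissue SD across beats (averaged within
batch, mean ± SD across batches), SD of tissue means within mold, SD of mold
means within batch, and the SD of batch means as a single number with no
dispersion of its own. The scheme is biased relative to true variance
components — each level's SD absorbs a share of the levels below it
(noticeable for the batch level, which rests on only 4 batch means) — and
the Monte-Carlo recovery test quantifies exactly that bias.

**Normality** is a one-sample KS test against a normal with the sample
moments (the platform's stated convention); this is conservative with
estimated parameters, and a Lilliefors-corrected option
(`lilliefors = TRUE`) is provided. **Dose tests** are two-tailed Student's
t-tests, paired by default since the same microtissues are measured before
and after exposure; zero-variance paired differences are flagged degenerate
rather than tested. No multiplicity correction is applied by default,
matching the per-comparison p < 0.05 convention of the source analyses; a
Holm option exists.

**Sample size** (`sample_size_for_change()`) finds the smallest n at which a
two-sided one-sample or paired t-test attains the requested power against
δ = relative change × mean, via `stats::power.t.test`'s noncentral-t
iteration. The published "n = 17 for a 10% APD change with 95% confidence"
cannot be reverse-engineered (the sidedness, the power/confidence
convention, and which SD entered it are unstated), so the function exposes
α, power and design explicitly instead of hard-coding a guess.

**Dose-response maps.** `sigma_shift_map()` expresses each tissue × dose ×
metric value as (value − control mean)/control SD; non-excitable tissues are
NA and render black, because when excitability is lost the other metrics
cannot be measured. `mean_difference_signature()` gives per (metric, dose)
the mean *paired* difference from control normalized by the metric's control
SD (σ_CTR) with paired-t significance; the control column is identically 0.

**The triangulation-slope indicator.** `tri_mxr_slopes()` fits, per dose, an
OLS regression of APD_tri on APD_MxR across tissues and compares each dose's
slope b to the control's with Z = (b_d − b_ctr)/√(SE_d² + SE_ctr²),
two-sided normal p. The Z statistic is asymptotically normal; at n = 35
points per fit its exact size is ≈5.5% (normal vs t critical value), which
is why the package's null-calibration checks run at n = 300 where the
asymptotic test applies. For the scenario analyses we flag slope changes at
p < 0.01, the threshold printed on the corresponding published slope
comparison. In the simulated dose series (lognormal CV-0.10 tissue-level
conductance jitter, 12 tissues/dose), I_Kr-surrogate block at {0.75, 0.55,
0.40} produces a strongly significant slope increase, while I_to block over
the same grades and moderate I_CaL augmentation {1.05, 1.10, 1.15} do not.
Strong I_CaL augmentation (≥ ~1.3×) genuinely steepens the slope in this
ionic model — the "unchanged slope" property is a statement about moderate
agonism, which is the regime the comparison describes.

# Problem sizes and numerical choices

Simulation sizes used by the test-suite and the acceptance script: 50
random waveforms for oracle equivalence (APD 100–600 ms, 979 Hz); one 8 s
64 × 64 movie at SNR 10 for segmentation recovery; 200 hierarchical
replicates for variance recovery; 5,000-rep null simulations for test
calibration; 20,000-rep power simulation; 12 tissues × 4 doses × 3 series
for the slope scenario. Seeds are explicit everywhere; no stochastic
function touches hidden global state beyond R's seeded RNG.

Degenerate inputs are first-class: constant traces fail capture; levels
never crossed yield NA APDs with the beat flagged; zero control SD flags the
metric column; slope fits with < 3 points or zero x-variance are NA;
constant input to the KS test and zero-length protocols are errors.

# Known limitations

* The waveform family is phenomenological; it does not emulate
  pacing-rate memory, alternans, or conduction within a tissue.
* The renderer's noise is additive Gaussian; EMCCD photon statistics are
  multiplicative in reality.
* The sequential-SD variance decomposition is not an unbiased
  variance-component estimator and is reported as the platform convention.
* The ionic model supports direction- and slope-level claims only; absolute
  APD values are not comparable to human tissue or to the (unnamed)
  simulation model of the source study.
* The EAD detector's thresholds (5% amplitude, 20 ms persistence) are
  package definitions; real dosing studies should report them alongside
  results.
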
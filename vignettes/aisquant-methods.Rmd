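---
title: "Quantifying AIS protein distribution and neuronal excitability with aisquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying AIS protein distribution and neuronal excitability with aisquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aisquant)
```

## The analysis

The axon initial segment (AIS) is the proximal axonal domain where action
potentials initiate. Its scaffold proteins — ankyrin G, βIV spectrin,
neurofascin, voltage-gated Na⁺ channels — are enriched at the AIS and
expressed at much lower levels in dendrites, and both the spatial extent and
the polarity of that enrichment remodel under kinase signaling. `aisquant`
implements a line-profile analysis of this enrichment, a per-neuron feature
representation suitable for single-cell classification of treatment, and
current-clamp feature extraction for the accompanying excitability
phenotype.

The pipeline quantifies, per neuron:

* the **analyte-specific AIS length** — the extent between the two points at
  which the smoothed, background-subtracted fluorescence profile falls below
  15% of its peak;
* the **integrated sum** — summed background-subtracted pixel intensity over
  a traced segment divided by the segment length (a mean intensity per µm);
* the **axo:dendritic ratio (adr)** — the AIS integrated sum divided by the
  dendritic integrated sum, a polarity index of subcellular distribution.

## Profile quantification

Starting from a sum-projected image (`sum_project()`), a rectangular ROI 3–4
pixels wide is traced along the AIS and averaged across its width into a 1-D
profile (`extract_profile()`). The mean of an off-neurite region is
subtracted from every point (`subtract_background()`); negative values are
retained, since clipping would bias low-signal dendrite sums upward. A
centered three-point moving average (`smooth_profile()`) is applied before
peak search; windows shrink at the profile edges so no samples are lost.
`detect_ais_boundaries()` takes the first index attaining the smoothed
maximum as the peak (ties broken proximally, which is deterministic and
matches the proximal origin of the trace) and walks outward until the
smoothed signal first drops strictly below 15% of the smoothed peak.

**Boundary placement.** The last above-threshold sample and its
below-threshold neighbour bracket the true threshold crossing. Reporting the
boundary at the last above-threshold sample itself quantizes each boundary
inward by up to one pixel — two pixels total, with a systematic −1 px bias —
whereas placing each unclamped boundary at the midpoint of the bracketing
pair keeps the length estimate within one pixel of the continuous
crossing-to-crossing extent for any peak position. `aisquant` uses the
midpoint convention; a boundary that never drops below threshold before the
ROI edge is clamped to the edge (flagged `clamped_start`/`clamped_end`), so
a profile that never leaves threshold spans the full traced ROI.

Integrated sums (`integrated_sum()`) use the **unsmoothed**
background-subtracted intensities — smoothing is a detection aid only, and
using it in sums would bias segment edges. The AIS sum runs over the
detected extent (the inclusive sample segment); the dendrite sum runs over
the full 15-µm dendritic trace with no boundary rule. The denominator is the
segment length in µm (`(end − start) × pixel size`); a pixel-count
denominator is available via `length_unit = "px"` since tracing tools report
either. Treated-group values are normalized to the control-group mean per
analyte (`normalize_to_control()`), and `log_transform()` prepares values
for group statistics (performed with standard external tools, not here).

## Per-neuron features and classification

`denoise_profile()` crops each AIS profile to its first 25 µm — controlling
for length differences between neurons — and applies the size-3 moving
average. `compute_features()` then computes four statistics of the denoised
profile plus the adr, a feature vector of length 5 per neuron:

| feature  | convention |
|----------|------------|
| iqr      | q75 − q25, linear-interpolation quantiles (type 7) |
| kurtosis | m₄/m₂² − 3 (Fisher excess, uncorrected central moments) |
| skewness | m₃/m₂^1.5 (uncorrected) |
| rms      | √(mean of squares) |
| adr      | raw by default; control-normalized via `normalized_adr = TRUE` |

The uncorrected-moment and interpolated-quantile conventions match common
time-series feature-extraction libraries; an alternative convention is a
one-line change where the moments are formed. Whether the adr entering the
classifier should be raw or control-normalized is not determined by the
procedure itself; raw is the default because normalization leaks a
group-level statistic into single-cell features.

`run_repeated_classification()` repeats, by default, 100 rounds of: draw a
uniform unstratified 70/30 split (train size `floor(0.7 n)`, which
reproduces the printed split sizes 56/24, 47/21 and 50/22 for n = 80, 68,
72), z-score features by the training-set mean/SD only (no test leakage),
fit a support-vector classifier, and score the held-out accuracy
(TP + TN over all classifications). The SVM uses a radial-basis kernel with
penalty 1 and kernel coefficient 1/n_features on the standardized features
(the common "scale" heuristic); kernel and penalty are exposed because the
original procedure does not pin them down. Zero-variance feature columns
fall back to unit scale with a warning. Each repeat derives its own child
seed by counter-based splitting, so repeat *i* is reproducible in isolation
and adding repeats never changes earlier ones.

## Electrophysiology

`generate_sweep_family()` simulates a leaky-integrator cell: membrane
voltage relaxes toward `rest + I·R/1000` mV (I in pA, R in MΩ) with time
constant τ, integrated with the exact exponential update so discretization
introduces no drift. When the voltage reaches threshold inside the current
step, a stereotyped action-potential template (half-cosine rise, default
100 mV over 0.7 ms; half-cosine decay to rest over 1.3 ms) is pasted and the
integrator resets — the template is a measurement target, not a biophysical
model, and its parameters are config. Measurement noise is added to the
recorded trace only, so stored ground truth stays exact. Protocols follow
the two standard step families: 500-ms steps at 10-pA increments for evoked
firing, and −120 to +20 pA in 20-pA increments at 200 ms for passive
properties.

Feature extraction (`extract_ephys_features()` and its parts):

* **Spike detection** — local maxima above 0 mV inside the step, ≥ 2 ms
  apart.
* **Current threshold (rheobase)** — smallest step amplitude with ≥ 1
  detected spike. The generator's ground truth is the closed form: the
  smallest amplitude whose deflection at the end of the step,
  `I·R/1000·(1 − e^{−T/τ})`, reaches the threshold–rest gap. (The end-of-step
  form is used rather than the asymptotic one because a step whose asymptote
  exactly equals the gap never crosses in finite time.)
* **Voltage threshold** — scanning backward from the first spike peak of the
  rheobase sweep, the voltage at the sample after the last one whose dV/dt
  is below 10 mV/ms. The central-difference derivative is averaged over 3
  samples before thresholding: at 20 kHz the raw derivative amplifies
  measurement noise by √2/dt (≈ 4 mV/ms per sample at 0.3 mV noise), enough
  to stop the scan one sample inside the upstroke; since the sub-criterion
  approach to threshold is slow, the averaging costs well under one sample's
  rise.
* **Input resistance** — OLS slope of steady-state voltage (mean over the
  last 25% of the step) against injected current, ×1000 to MΩ, excluding any
  spiking sweep. With τ = 50 ms and 200-ms steps the last-25% window leaves
  a ≈ 3.2% settling deficit — visible in the recovery numbers and inherent
  to the protocol, not to the estimator; shorter τ recovers exactly.
* **Membrane time constant** — Levenberg–Marquardt fit of
  `a + b·e^{−t/τ}` to the onset transient of the smallest-magnitude
  hyperpolarizing step; capacitance follows as `1000·τ/R` (pF).
* **Waveform features** — upstroke = max dV/dt between threshold and peak;
  downstroke = min dV/dt between peak and the after-spike minimum; latency =
  first spike peak time − step onset. At dt = 0.05 ms the discrete
  derivative recovers the template slopes within ~1%; estimates converge to
  the template values as dt → 0 (tested at 0.2, 0.1, 0.05 ms).

## The synthetic cohort generator

No parametric model of the AIS profile accompanies the original procedure —
only its qualitative shape: a rise from the soma to a single dominant peak
and a distal decay. `ais_bump_model()` uses a difference of two logistic
sigmoids (a plateau) multiplied by a linear taper that tilts the peak
proximally; the plateau width is calibrated by root finding so that the two
15%-of-peak crossings of the unit-peak bump are exactly the requested
length apart. This makes the *true* length a designed quantity, not a
by-product. The dendrite is a flat 15-µm segment, per the standard dendrite
tracing convention.

Cohorts add two layers of randomness:

* **Pixel noise** (`noise_sd`, default 8 a.u. against a 100 a.u. peak) —
  additive Gaussian detector noise. A Poisson option is deliberately left
  out; at the photon counts of summed Z-stacks the Gaussian approximation is
  adequate for what the tests probe.
* **Between-cell variability** — per-cell AIS amplitude and dendrite level
  scale by unit-mean lognormal factors (`cell_cv`, default 0.25) and the
  per-cell true length jitters (`length_sd_um`, default 2 µm). These
  defaults emulate the cell-to-cell spread visible in real cohorts, where
  treatment effects overlap heavily and single-cell classification
  accuracies land in the 60–75% range rather than near 100%. Without
  between-cell variability, per-neuron features are nearly deterministic
  and any nonzero effect classifies perfectly — a regime that says nothing
  about the method. Set both to 0 for exact noiseless constructions.

Treatment effects enter as `effect = list(length_delta_um, ais_scale,
dendrite_scale)` applied to the treated condition — AIS shortening, AIS
intensity scaling, dendritic intensity scaling, the three effect axes the
imaging phenotype comprises. Seeding is counter-based: record *i* of each
condition derives its seed from the cohort seed and *i* alone, so enlarging
a cohort never changes existing records.

Every record stores its ground truth: the designed length, peak position
and amplitude, dendrite level, and a reference quantification of the
noiseless profile computed by an independent plain-loop implementation of
the smoothing/peak/boundary/sum rules. At `noise_sd = 0` the production
path must reproduce these values (length within one pixel of the continuous
extent; adr to 1e-6), which the test suite asserts record by record.

`render_image()` paints a record's profile along a straight horizontal
neurite of configurable width on a constant background, optionally blurred
(Gaussian PSF approximation) and noise-added, with 0-based half-open ROI
rectangles for the neurite and a background region — enough to exercise the
image-side operations end to end. It does not attempt realistic optics,
curved or branching neurites, or crossing AISs; profiles from such images
are out of scope (real tracing handles them manually).

## What passing tests do and do not show

The synthetic cohorts share the statistical *structure* the analysis
assumes — unimodal AIS enrichment, flat dendrites, additive noise,
lognormal cell variability, multiplicative treatment effects — but none of
the nuisance structure of real micrographs: uneven illumination, varying
background, neurite curvature, out-of-focus light, or chromatic offsets.
Green tests therefore validate the computational contract (the estimators
recover known truth under the stated model, the classifier behaves at
chance under the null and orders effect sizes) — they do not certify
accuracy values on real imaging data, which depend on those nuisances and
on manual tracing quality.

## Numerical choices and degenerate inputs

* Peak ties break to the first (most proximal) index.
* A profile whose smoothed maximum is ≤ 0 raises an explicit
  "no AIS detected" error; zero-length integration segments and
  double background subtraction are errors, not silent results.
* A dendrite integrated sum ≤ 0 flags the adr undefined rather than
  returning an infinity.
* Zero-variance profiles make skewness/kurtosis undefined and raise an
  error naming the problem; non-finite adr values are rejected.
* Single-class training draws in a split are scored at chance with a
  warning rather than aborting the repeat harness.
* The exponential fit for τ starts from moment-based initial values and
  fails loudly if the optimizer does not converge or returns τ ≤ 0.

Test problem sizes are chosen to exercise every contract while keeping the
suite fast: cohorts of 8–40 neurons per condition, 100-repeat
classification runs for behavioral claims and 10–20 repeats for invariance
checks, three-cell recovery grids at dt = 0.05 ms, and 200-case randomized
oracle-equivalence sweeps per numerical kernel.

## Reproducible runs

`validate_config()` merges a YAML document over the defaults, rejects
unknown keys, range-checks invariants, and generates (and records) a seed
when none is given. `run_pipeline()` executes
simulate → quantify → features → classify → ephys, stamping every CSV/JSON
output with the md5 hash of the canonical config serialization and writing
a manifest of output checksums; two runs with the same config and seed are
bit-identical (the timestamped log aside). Each stage can also re-run from
the previous stage's serialized outputs (`paths.cohort_csv`) with identical
results. A thin command-line wrapper lives at
`system.file("scripts", "ais-pipeline.R", package = "aisquant")`.

## Known limitations

* The AIS profile model is single-peaked by construction; multi-peaked or
  beaded profiles (which occur in pathology) are not generated and the
  15% rule is not validated against them.
* The AIS start is taken from the trace origin; identifying it from a
  second channel's fading (as done manually in practice) is out of scope.
* The leaky integrator has no conductances; spike shape is a template, so
  waveform features validate the measurement code, not spike biophysics.
* Group-level inference (nested ANOVA, multiple-comparison corrections) is
  delegated to standard statistical tools.
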
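# aisquant

Quantification of axon-initial-segment (AIS) protein distribution from
fluorescence line profiles, single-neuron treatment classification, and
current-clamp feature extraction — with a ground-truth synthetic-data
generator and a reproducible pipeline runner.

## The problem

The AIS is the proximal axonal domain where action potentials initiate. Its
scaffold proteins (ankyrin G, βIV spectrin, neurofascin, Nav channels) are
enriched at the AIS and sparse in dendrites; kinase signaling remodels both
the spatial extent and the polarity of that enrichment, with functional
consequences for firing. Quantifying this from confocal images is done with
intensity line profiles traced along the AIS and a dendrite. `aisquant`
implements that analysis for anyone working with such profiles (or images
plus rectangular ROIs), plus the downstream single-cell classification and
patch-clamp feature extraction that typically accompany it.

Per neuron, from the background-subtracted profile *I(x)*:

- **analyte-specific AIS length** — with the three-point smoothed profile
  *Ī(x)* and its peak *Ī(x_pk)*, the extent between the two positions where
  *Ī(x)* falls below 0.15 · *Ī(x_pk)*;
- **integrated sum** — Σ *I(x)* over a traced segment divided by segment
  length (a.u./µm);
- **axo:dendritic ratio (adr)** — AIS integrated sum over the detected
  extent ÷ dendrite integrated sum over the full 15-µm dendritic trace.

For classification, each neuron's first 25 µm of AIS profile is low-pass
filtered (moving window of 3) and summarized as a feature vector of length
5 — interquartile range, excess kurtosis, skewness, root mean square, adr —
and a support-vector machine is trained and tested over repeated random
70/30 splits (train size ⌊0.7 n⌋), reporting mean ± SD accuracy, where
accuracy = (TP + TN) / all classifications.

From current-clamp sweep families (square steps; 500 ms / 10 pA increments
for firing, −120..+20 pA / 20 pA / 200 ms for passive properties):
rheobase, voltage threshold (first dV/dt > 10 mV/ms of the first evoked
spike), input resistance (OLS slope of the steady-state V–I relationship),
membrane time constant (exponential onset fit), capacitance (τ/R),
upstroke/downstroke velocities, latency to first peak, maximum spike count
and firing frequency.

## Worked example

```r
library(aisquant)

# A two-condition synthetic cohort: 40 neurons per condition; the treated
# condition has a 4 um shorter AIS, 1.5x AIS intensity, 1.2x dendrite
# intensity, with realistic cell-to-cell variability and pixel noise.
cfg <- cohort_config(n_per_condition = 40, seed = 7,
                     effect = list(length_delta_um = -4, ais_scale = 1.5,
                                   dendrite_scale = 1.2))
cohort <- generate_cohort(cfg)

# One neuron end to end
q <- quantify_neuron(cohort[[1]])
sprintf("AIS length %.2f um, adr %.2f", q$ais_length_um, q$adr)
#> "AIS length 17.08 um, adr 2.86"

# Cohort quantification, normalized to the control mean
quant <- normalize_to_control(quantify_cohort(cohort))
aggregate(cbind(ais_length_um, adr, normalized_ais) ~ treatment, quant, mean)
#>   treatment ais_length_um      adr normalized_ais
#> 1   control        19.068 3.618478       1.000000
#> 2   treated        15.862 4.525890       1.533354

# 5-feature vectors and repeated 70/30 SVM classification
feats <- feature_table(cohort)
run_repeated_classification(
  feats[, c("iqr", "kurtosis", "skewness", "rms", "adr")], feats$label,
  n_repeats = 100, seed = 7
)
#> <classification_result> 100 repeats of 56/24 splits: accuracy 85.1% +/- 6.6% (mean +/- SD)
```

The treated group is shorter (15.9 vs 19.1 µm), brighter at the AIS
(normalized intensity 1.53) and — because the dendrite scaling is smaller
than the AIS scaling here — higher in adr; with this effect size the
classifier separates the conditions in 85% of held-out cells.

Electrophysiology on a simulated cell (600 MΩ, τ = 50 ms, 0.3 mV noise):

```r
firing  <- generate_sweep_family(cell_config(rin_mohm = 600, tau_ms = 50,
                                 noise_sd_mv = 0.3, sample_interval_ms = 0.1,
                                 seed = 7))
passive <- generate_sweep_family(cell_config(rin_mohm = 600, tau_ms = 50,
                                 protocol = passive_protocol(),
                                 noise_sd_mv = 0.3, sample_interval_ms = 0.1,
                                 seed = 7))
extract_ephys_features(firing, passive)
#>   cell_id voltage_threshold_mv current_threshold_pa rin_mohm   tau_ms
#> 1    cell            -39.98401                   40 580.9832 49.88689
#>   capacitance_pf upstroke_mv_per_ms downstroke_mv_per_ms latency_ms max_spikes
#> 1       85.86632           213.0086            -145.8822       90.2         22
#>   max_freq_hz
#> 1          44
```

The cell's true threshold is −40 mV and true rheobase 40 pA; the recovered
input resistance sits ~3% low because the steady-state window (last 25% of
a 200-ms step) is not fully settled at τ = 50 ms — see the methods
vignette (`vignettes/aisquant-methods.Rmd`) for this and every other
numerical convention.

## Pipeline and CLI

```r
run_pipeline(list(seed = 1), "runs/demo")   # all stages, defaults
```

writes `cohort_profiles.csv` (+ ground-truth JSON), `quant_results.csv`,
`features.csv`, `classification_report.json`, per-cell sweep CSVs,
`ephys_features.csv`, a run log and a `manifest.json` with output
checksums; every output is stamped with the md5 hash of the config, and a
given config + seed reproduces every byte. The same runs from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/ais-pipeline.R", package="aisquant"))')" \
  all --seed 1 --out runs/demo
```

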
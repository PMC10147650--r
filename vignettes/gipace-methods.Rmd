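---
title: "Slow-wave electrical features and adverse-effect classification: methods"
author: "gipace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-wave electrical features and adverse-effect classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gastrointestinal (GI) motility is paced by rhythmic extracellular
electrical activity — slow waves — generated by the interstitial cells of
Cajal and recordable across a tissue with a microelectrode array (MEA).
Acute drug exposure changes the rhythm's frequency, amplitude, waveform
shape, regularity and spatial propagation in ways that are reproducible
for a given compound. `gipace` operationalizes a screening idea built on
that observation: characterize every (drug, dose, tissue, repeat)
recording by a fixed panel of 24 *electrical features* (EFs), express
drug action as the change of each feature from its pre-drug baseline,
merge those profiles with a SIDER-style table of clinically reported
adverse effects (AEs), and train binary classifiers that predict, for a
new compound, the probability that it induces each AE.

Because MEA drug-screen recordings are not publicly deposited, the
package ships a first-class synthetic-study generator. It is not an ICC
network model; it is a controlled stand-in whose planted effects are
known exactly, so every downstream stage — extraction, normalization,
labelling, training, validation, reporting, network construction — is
testable end to end.

## The 24 electrical features

The feature panel covers four aspects of the signal. Per-channel scalar
features are aggregated across electrodes by the median (robust to dead
channels); spatial features use the grid jointly.

* **Waveform (7)** — dominant frequency (argmax of the Welch power
  spectrum in the 0.5–60 cpm analysis band, ties resolved toward the
  lower frequency), average frequency (60·(n−1)/elapsed time between
  first and last detected peak), dominant power (power in the peak bin,
  µV²), amplitude (mean peak-to-trough, µV), period (mean inter-peak
  interval, s), slope (mean maximum upstroke rate, µV/s) and propagation
  velocity (µm/s).
* **Rhythm distribution (3)** — percentages of analysis-band spectral
  power below, inside and above the tissue's *normal* band, defined
  relative to the tissue base frequency f0 as [0.5·f0, 1.5·f0]. Relative
  bands transfer across tissues with very different base rates; the three
  percentages sum to 100 by construction.
* **Complexity (8)** — multiscale sample entropy at scales 1–5 (m = 2,
  tolerance r = 0.15 × SD, non-overlapping-mean coarse-graining) and
  three detrended-fluctuation exponents (order-1 detrending of the
  integrated profile; windows 4–16, 16–64 and 4–64 samples). When no
  extended template match exists the sample entropy is undefined; a
  finite cap `log(B(B−1)+1)` is substituted and flagged so downstream
  t-tests stay usable.
* **Propagation (6)** — each detected wave's onset-lag field is
  classified as forward, backward, radial, colliding or unorganized;
  the five percentages (summing to 100) plus a pattern-change index,
  1 − (modal pattern fraction).

Tissue base frequencies default to stomach 5, duodenum 17, ileum 12 and
colon 7 cpm — order-of-magnitude GI values. Only *changes* relative to
baseline matter downstream, so their exact values are not critical.

### Signal-processing choices

*Band-pass.* Channels are filtered to 0.5–60 cpm by zero-phase spectral
masking with raised-cosine transitions (20% of each edge). All channels
are filtered in one FFT, which keeps whole-study extraction tractable on
a single core.

*Spectra.* Welch averaging with Hann windows of eight dominant periods,
50% overlap, and zero-padding so the frequency grid resolves 0.5 cpm.
The quality gate computes its peak-to-median ratio on the *unpadded*
grid, where bins are nearly independent and a flat (no-rhythm) spectrum
cannot manufacture a sharp peak from interpolation.

*Events.* Peaks on the band-passed trace need prominence ≥ 3 × the noise
MAD (estimated from first differences) and are separated by a refractory
interval of half the dominant period; troughs and maximum-upstroke onsets
are located between consecutive peaks.

*Velocity.* Cross-correlation lags of the 112 adjacent electrode pairs
(horizontal + vertical neighbours on the 8×8 grid), each wrapped to
within half a dominant period and refined by parabolic interpolation,
are fit by least squares to the electrode coordinate differences; speed
is the reciprocal gradient magnitude. Adjacent pairs — rather than all
2016 pairs — keep every lag well below half a period even for the
fastest tissue (duodenum, 17 cpm), where lags across the full grid span
a whole cycle and would alias. A synchronous array (near-zero gradient)
is capped at 50 mm/s and flagged.

*Per-wave onset fields.* For pattern classification the per-channel peak
matching grows outward from the centre electrode, each channel adopting
its peak nearest the mean of its already-assigned neighbours (within
half a period). This region-growing unwrap is what makes short-period
tissues classifiable; naive nearest-peak matching aliases across cycles.
A plane fit with R² ≥ 0.7 whose direction lies within ±45° of the
longitudinal (column) axis is forward (opposite: backward); otherwise a
radial fit from the best interior source (R² ≥ 0.7, outward) is tried,
then opposing half-grid plane fits (colliding); anything else is
unorganized.

*Complexity decimation.* Entropy and DFA are computed on the band-passed
trace decimated to 2 Hz — the analysis band tops out at 1 Hz, so
subsampling the already band-limited signal cannot alias — on eight
evenly spaced electrodes. Sample entropy on a heavily oversampled smooth
signal is dominated by trivial continuity matches; 2 Hz both removes
that artefact and makes the O(n²) template count cheap. At the default
300 s this gives 600 samples, comfortably above the 4 × 64-sample
minimum for the DFA window range (recordings must be ≥ ~130 s).

*Quality gate.* A recording is rejected when more than half its channels
are flatline (SD < 1 µV), when the centre channel's unpadded Welch
spectrum has no analysis-band peak ≥ 4 × the in-band median power, or
when the median peak-to-peak span is below 5 µV. All thresholds live in
`ef_config()` and can be loaded from YAML.

## Normalization and learning datasets

Unit-bearing features become percentage changes,
(X_post − X_baseline)/X_baseline × 100. Features already expressed as
percentages of contribution are differenced in percentage points. The
unit-free complexity features (entropy scales, DFA exponents) and the
pattern-change index are also differenced: they can legitimately be zero
at baseline (a clean rhythm has near-zero entropy and a single-pattern
recording has change index exactly 0), where a ratio would be undefined
and would discard exactly the cleanest recordings.

Labels follow the SIDER merge rule: a (drug, AE) pair is 1 when a
side-effect row exists, forced to 0 when an indication row exists
(drugs prescribed *for* a condition generate false AE reports from
pre-existing disease). AEs with balance ratio (positives/total drugs)
below 0.25 or above 0.75 are excluded as imbalanced; boundary values are
retained (the exclusion rule is strict).

Three dataset kinds are built per AE: *full* (one row per (drug, dose,
tissue, repeat), 24 features), *averaged* (one row per (drug, dose);
repeats averaged per tissue and aligned into 96 tissue-prefixed columns,
with missing tissues left as NA), and *tissue-split* (the full rows
partitioned by tissue, plus an optional intestine grouping). Averaging
happens after normalization: each repeat is normalized against its own
baseline first, so baseline drift between preparations does not leak
into the average.

## Classification protocol

Features are refined per AE by a pooled-variance two-sample Student
t-test (positive vs negative rows), keeping p < 0.05 with no
multiple-testing correction — the screen is deliberately permissive and
the per-feature p-values are returned so users can re-filter. Selection
precedes splitting, as in a two-stage refine-then-train pipeline; the
random-dataset control (below) is subjected to the same selection, so
any selection optimism affects both arms equally.

Five classifier families are used behind a common surface: Gaussian
naive Bayes, linear discriminant analysis, a Gini classification tree
(minimum leaf 3), 5-nearest-neighbours on z-scored features, and a
linear-kernel SVM (unit cost) whose margins are mapped to [0, 1] by a
logistic link oriented on the training data. Full datasets use only
naive Bayes, tree and KNN; averaged and tissue-split datasets use all
five unless missing features rule out the discriminant and SVM. An
ensemble averages the members' *binary* votes. Every probability/score
threshold in the package is strict (`> 0.5`), so exact ties vote
negative.

Each protocol run draws seven randomized half/half splits (row-wise,
stratified by label so toy-sized datasets cannot go single-class; a
drug-wise split mode is available because row-wise splitting shares a
drug's repeats across halves). Accuracy, TPR and TNR are recorded per
(seed, algorithm), along with the training-half drug coverage; models
whose mean coverage is ≤ 80% are flagged. The best model is the
(seed, algorithm) with highest test accuracy, ties broken by higher TPR
then lower seed.

*Random-dataset validation.* A control dataset resamples every feature
column i.i.d. from a normal with the column's mean and sample SD,
keeping labels and shape. The control runs the identical protocol under
the same split seeds. A real model passes validation only when it beats
its control by more than 0.5 accuracy points in either the mean or the
best accuracy across seeds — or when the control fails to select any
significant feature at all. Models failing validation are excluded from
reports.

## Prediction refinement and reports

For a drug's rows, each of the seven per-seed models votes per row;
votes are averaged within (drug, dose) (strict majority), then combined
across doses by the fixed weights 1, 0.5, 0.3, 0.1, 0.05 in descending
dose order (weighted mean, strict threshold) — repeat averaging first,
dose weighting second; the composition order is fixed and matters, since
the two operators do not commute. With fewer than five doses the first
k weights are used so the highest dose always carries weight 1. The
reported probability is 100 × positives/7 — always a multiple of 100/7,
e.g. 3/7 → 42.9% (rounded 43%), 1/7 → 14%. The exact fraction is kept in
the CSV; the human-readable summary rounds to integer percent.

## Drug–AE network

Per-drug mean refined features (z-scored) place each drug in a
similarity space; two pole nodes sit at the positive- and
negative-labelled centroids. The pole separation (Euclidean distance
between centroids) summarizes how well the refined features distinguish
the classes; every drug links to both poles with weight 1/(1+distance),
and the top 10% most similar drug pairs get drug–drug edges. The
receptor-class clustering score is the fraction of drugs whose nearest
neighbour shares their receptor class. Euclidean distance on z-scored
features is this package's choice — no canonical metric exists for this
construction — and is recorded in the export metadata. Layout is left to
the consumer (GraphML); only distances and weights are contractual.

## The synthetic-study generator

Each drug has a per-tissue effect map: multiplicative factors on
frequency, amplitude, upstroke slope (implemented as harmonic content)
and velocity, plus an additive period-jitter irregularity. Libraries
have receptor-class structure: class centroids are drawn with SD 0.15
(log scale) and drugs scatter SD 0.05 around their centroid, so
within-class effect maps are closer than between-class maps — the
property the network clustering score measures.

A recording is a travelling plane wave along the grid's longitudinal
axis: a fundamental at the tissue base frequency plus one harmonic at
25% amplitude, per-cycle period jitter (SD 3% of the period) shared
coherently across channels, additive white noise (SD 10 µV against a
100 µV wave), at 10 Hz for 300 s on an 8×8 grid with 300 µm pitch and a
600 µm/s baseline propagation speed. Dose–response is monotone: at the
k-th dose from the bottom of n, multipliers are raised to the power k/n,
so the highest dose exerts the full effect.

Planted AE rules draw positives at a configured prevalence and shift the
affected effect-map entries by d × (the library's between-drug SD), so
`d` reads as a drug-level Cohen's d. The stock excitatory rule raises
colonic frequency and amplitude and lowers stomach amplitude; the stock
inhibitory rule suppresses duodenal slope, amplitude and frequency —
mirroring the excitatory/inhibitory AE contrast structure this kind of
screen reports. A configurable fraction of positives also emit
indication rows to exercise the override.

Determinism is end-to-end: every recording's RNG stream derives from the
master seed and a stable hash of (drug, dose, tissue, repeat, phase), so
studies are reproducible regardless of generation order.

**What the generator does not emulate.** Real MEA data have correlated,
non-Gaussian noise, electrode drift and dropout, non-planar and
multi-source propagation, tissue heterogeneity, and drug effects that
are not separable per-tissue multipliers. Passing the planted-recovery
benchmarks therefore demonstrates that the pipeline's machinery is
correct and unbiased — not that any particular accuracy is attainable on
laboratory recordings.

## Benchmark studies and problem sizes

Two canonical studies (`planted_benchmark_study()`) are used by the test
suite and the acceptance script:

* *classification*: 40 drugs × 4 receptor classes × 3 tenfold doses ×
  4 tissues × 3 repeats (1440 normalized rows, 2880 recordings at the
  300 s default), excitatory rule at d = 1, prevalence 0.5 — a
  moderate-signal benchmark for the protocol and its validation control.
* *network*: 16 drugs × 2 classes at 150 s with d = 3 — a
  well-separated benchmark for pole agreement and receptor-class
  recovery.

These sizes were chosen as the smallest studies at which drug-level
effects, dose attenuation and class structure are all simultaneously
resolvable; the classifier benchmarks train on the full dataset kind,
which the protocol comparisons identify as the strongest configuration.

## Degenerate inputs and numerical conventions

Zero baselines on unit-bearing features exclude the row (logged) rather
than producing infinities. Constant series have zero entropy by
convention and zero DFA fluctuation exactly. Zero-variance feature
columns z-score to zero (scale clamped to 1). Equal spectral peaks take
the lower frequency; exact 0.5 scores vote negative everywhere; KNN
distance ties are resolved by the underlying library under a seeded RNG
state so predictions are reproducible. A single-drug feature matrix
skips z-scoring and is flagged rather than producing NaNs.

## Known limitations

The classifiers are not calibrated — reported probabilities are vote
fractions, not calibrated risks. Row-wise splitting shares repeats of a
drug across train/test halves; the drug-wise mode removes that sharing
at the cost of much coarser randomization on small studies. The t-test
screen ignores feature correlation and multiplicity. The 24-feature
panel and all rhythm-band / window constants are fixed conventions of
this implementation; alternative conventions would yield systematically
different (though comparable) feature values.
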
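---
title: "Methods: voltage-based LVH detection from 12-lead ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voltage-based LVH detection from 12-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecglvh)
```

## The problem

Left ventricular hypertrophy (LVH) is thickening of the left
ventricular wall. The diagnostic standard is echocardiographic: the
left-ventricular mass index (LVMI), with LVH defined as LVMI strictly
above 115 g/m² in men and 95 g/m² in women (`lvh_label()`). On the ECG,
hypertrophy manifests as increased QRS voltages, which is what both the
classical voltage criteria and the classifiers in this package read.
The package covers the whole chain — amplitude extraction from raw
12-lead samples, feature construction, rule-based criteria, and
learning-based classification — and ships a synthetic generator with
exact ground truth so that each link can be verified independently of
any clinical dataset.

Records are modelled on a common acquisition convention: 500 Hz
sampling for 11 s, i.e. 5500 samples per lead, amplitudes in mV. All
sample indices in this package are 1-based (the R convention), including
printed and exported indices; exported CSVs label columns accordingly.

## R-peak and S-valley detection

`detect_lead()` composes three steps, all parameterised by
`detector_params()`:

1. **Preliminary R scan** (`detect_preliminary_r()`). Walk the signal
   left to right; accept a sample that (a) exceeds the minimum peak
   amplitude `mpa` = 0.025 mV, (b) is a strict local maximum, and (c)
   lies at least the refractory interval `miR` = 0.6 s (300 samples at
   500 Hz — the longest RR interval of the normal 60–100 bpm range)
   after the previous acceptance. The scan is *greedy*: the first
   qualifying sample after each refractory period wins, not the tallest
   candidate in a window. A flat-topped apex (a run of equal samples
   higher than both neighbours) is accepted at the run's last sample;
   the strict-inequality reading would silently drop such beats, and on
   continuous-valued signals the two readings coincide.
2. **S-valley location** (`locate_s_valley()`). The S valley is the
   minimum of the half-open window extending 0.12 s after the R peak —
   the interval within which the S valley of a QRS complex normally
   falls. Argmin/argmax ties resolve to the earliest index, keeping the
   scan-order semantics deterministic.
3. **T-misdetection correction** (`correct_t_misdetection()`). When a T
   wave is taller than its R peak a peak scanner can accept the T apex
   as an R. The check: if the minimum of the 0.25 s window *before* the
   putative R is lower than the current S valley, the putative R was a
   T; the S valley moves to that minimum, the R is re-located as the
   maximum of the 0.12 s window adjacent to the updated S, and a fresh
   forward S search from the new R restores R-before-S ordering. The
   adjacency direction is a genuine ambiguity: one reading searches
   forward from the updated S, the other backward ("before" it). We
   default to **backward** because in a QRS complex the R precedes its
   S, and a forward search from the corrected S would often re-find the
   very T peak being corrected; the forward variant remains available
   via `detector_params(step7_direction = "forward")` for comparison.

Window lengths are `round(duration × fs)` samples (half-up): 60 and 125
samples at 500 Hz for the 0.12 s and 0.25 s windows. No filtering or
baseline-wander removal precedes detection; the algorithm operates on
raw samples, so input is assumed to be hardware-filtered,
diagnostic-quality ECG.

Two consequences of the greedy scan are worth stating plainly, because
they bound where the detector can be trusted:

* **Everything above `mpa` is a candidate.** There is no P-rejection
  and no band-pass stage, so any local maximum above 0.025 mV — a
  physiological P wave (typically 0.1–0.25 mV), or baseline noise whose
  excursions cross the floor — is accepted if it falls outside the
  refractory period, and each false acceptance then masks the true R
  behind a 0.6 s refractory shadow. The synthetic defaults therefore
  keep the P amplitude at 0.01 mV and noise at 0.004 mV sd; tests that
  add noise stay in that regime. With physiological P amplitudes the
  greedy scan locks onto P waves — a limitation of the detection rule
  itself, which the generator can demonstrate (raise `p_amp`) but not
  repair.
* **T misdetection requires a masked R.** On a clean periodic signal
  the R apex is always the first qualifying candidate of its beat, so a
  taller T is only *accepted* when the true next R falls inside the
  refractory window, i.e. RR < 0.6 s. The correction suite therefore
  simulates 105–115 bpm with T/R ratios 1.1–1.5; at normal rates the
  correction step verifiably leaves already-correct beats unchanged
  (its trigger condition fails because the backward window's minimum,
  usually the Q valley, sits above the S valley).

The preliminary scan is tested for exact equivalence against an
exhaustive element-by-element oracle on 1,000 random signals, and the
correction suite demands exact recovery of the true R index on 100/100
simulated T>R records.

## Features

`median_amplitudes()` drops the first and last detected cycles of each
lead (edge beats may be truncated or noisy) and takes per-lead medians
of the interior R amplitudes and S-valley magnitudes — 24 features, R
and S per lead, in mV. The S feature is the *depth* of the valley:
`max(0, -s)`, floored at zero when no downward deflection exists. The
floor matches how the criteria consume "S amplitude" (a magnitude added
to R amplitudes against mV thresholds) and the clinical usage of, e.g.,
"SV1". Raw signal zero is the baseline; no isoelectric-PR correction is
applied, because the amplitude-extraction rule defines none.

`segment_beats()` augments data by emitting one 24-feature row per
*interior* beat of a reference lead (default II, the conventional
rhythm lead), so the row count is always `n_R(reference) − 2`. Other
leads contribute their own beat's amplitudes, matched one-to-one to the
nearest reference R index within a 0.15 s tolerance (configurable; the
matching rule is this package's definition — a per-beat vector could
equally reuse case medians for non-reference leads, and a lead-beat
that finds no match inside the tolerance does exactly that). Every beat
row inherits its case's label.

`zscore_fit()` / `zscore_apply()` normalise features to mean 0, sd 1
using the **population** (n-denominator) sd, clamping sd < 1e-12 to 1
so constant columns map to zeros. Statistics are fitted on training
rows only and reused for test rows; fitting on pooled train+test would
leak test-set location/scale into training.

## The seven voltage criteria

Each criterion maps a feature vector (plus sex where the thresholds are
sex-specific) to a score, a threshold, and a boolean call. Thresholds
live in one table (`lvh_criteria_thresholds()`), so recalibration never
touches code. Printed strictness is preserved exactly and audited
boundary-by-boundary in the tests:

| criterion | rule (mV) | strictness |
|---|---|---|
| Cornell | SV3 + RaVL > 2.8 (m) / 2.0 (f) | strict |
| Sokolow–Lyon | SV1 + max(RV5, RV6) ≥ 3.5 | non-strict |
| Peguero–Lo Presti | deepest S any lead + SV4 ≥ 2.8 (m) / 2.3 (f) | non-strict |
| Framingham | any of 5 clauses (RaVL > 1.1; RV4/5/6 > 2.5; SV1/2/3 > 2.5; max(SV1,SV2)+max(RV5,RV6) > 3.5; RI+SIII > 2.5) | strict |
| Gubner | RI + SIII ≥ 2.2 | non-strict |
| Sum of 12 leads | Σ per-lead max(R, S) ≥ 17.9 | non-strict |
| Lewis | (RI + SIII) − (RIII + SI) > 1.7 | strict |

Notes: Peguero's "deepest S in any lead" may be SV4 itself, which then
counts twice — that is the printed definition. aVR's amplitudes
participate only in the deepest-S scan and the 12-lead sum, the two
rules whose wording covers "any"/"each" lead. Framingham's
"max(SV1 or SV2)" is read literally as the larger of the two, and the
result records which clauses fired. All criteria except Lewis are
monotone: raising any constituent amplitude never turns a positive call
negative (a property test).

## Classifiers

`lvh_model(x, y, method = …)` fits one of three models and returns a
classed object with `print`, `summary`, `predict`, and
`evaluate_model()` support. Every stochastic step runs under a local,
restored RNG stream derived from `seed`, so (data, seed) reproduces a
fit bit-exactly.

* **Entropy decision tree.** Node impurity is the binary entropy
  `−p log₂ p − q log₂ q` (`node_entropy()`; 0 for a pure node, 1 at
  p = 0.5). For each depth 1–25, mean tenfold-CV accuracy is computed
  on the training rows; the best depth wins, with ties broken toward
  the *smallest* depth (parsimony), and the final tree is refit on all
  training rows. The trees themselves come from `rpart` with
  information-gain splits and `cp = 0`, leaving depth as the only
  complexity control.
* **k-means++ classifier.** k-means++ seeding (first centre uniform,
  subsequent centres drawn with probability proportional to squared
  distance from the nearest chosen centre) followed by Lloyd iterations
  via `stats::kmeans`; `k = 2` for the binary task. Each cluster is
  assigned its majority training label; prediction is
  nearest-centroid. This is clustering used as a classifier — a
  deliberately weak baseline.
* **Back-propagation network.** 24 inputs → 26 logistic hidden units →
  1 sigmoid output, binary cross-entropy, mini-batch gradient descent.
  The architecture, 400 epochs, tenfold CV, and z-scored inputs are the
  protocol's stated choices; the remaining specifics are this package's
  own defaults, stated as such: learning rate 0.01, batch size 32,
  Glorot-uniform initialisation, threshold 0.5 on the output unit.
  Training diverging to non-finite weights raises an error rather than
  returning a silent NaN model.

Evaluation uses a 7:3 train:test case split (`split_plan()`,
`train_test_split()`) and confusion-matrix metrics with LVH as the
positive class (`model_report()`); a ratio with a zero denominator is
reported as `NA`, never 0. `balanced_cohort()` implements the
one-control-per-case down-sampling design. For beat-level rows the
split is **grouped by subject** whenever a grouping vector is passed:
beats from one subject are near-duplicates, and letting a subject span
train and test inflates headline accuracy. The protocol this package
models does not state whether its split preceded segmentation, so the
grouped split is the default and the ungrouped variant remains
available (`group = NULL`) for comparison — the choice materially
affects beat-level numbers.

One printed formula deserves a note: the source formulation of the
node impurity reads "p·log₂p − q·log₂q", which evaluates to 0 at
p = q = 0.5 while the accompanying text requires the value 1 there. The
standard negated form, consistent with the text and with both stated
endpoints, is what `node_entropy()` implements.

## Feature importance

`f_statistic()` is the classical one-way ANOVA ratio of between-group
to within-group variance; it is authored directly from the definition
and tested against R's `anova(lm(...))` to 1e-10 relative tolerance on
1,000 random instances. Perfectly separated constant groups yield
`Inf` explicitly. `rank_features()` ranks the 24 features by two-group
F (LVH vs non-LVH), stable in canonical feature order on ties; the F
value is invariant under per-feature affine rescaling, so no
normalisation is needed first. `elimination_curve()` fixes the ranking
once, then for k = 24 … 1 retrains on the top-k features and records
held-out accuracy on one fixed split (same split for every k, for
comparability). A re-rank-each-step mode (`rerank = TRUE`) exists; the
fixed-ranking mode matches the sequential-exclusion protocol.

## The synthetic generator

`synth_record()` renders each lead as a sum of per-beat Gaussian bumps
(P, Q, R, S, T; `beat_template()`) at RR-spaced apex times with
optional seeded RR jitter, white noise, and sinusoidal baseline wander.
Gaussian morphology was chosen over dynamical-system ECG models
because it yields *exact* ground truth: the truth tables carry the
apex/valley indices and amplitudes of the noiseless rendering,
extracted with the same argmax/argmin conventions the detector uses, so
detector tests can demand exact index equality. Defaults: 500 Hz, 11 s,
first apex at 0.35 s, per-lead templates with roughly physiological
relative amplitudes (tall R in II/V4–V6, deep S in V1–V3, aVR with
small r, deep S, and inverted T to exercise signed-amplitude handling).
Templates whose ±2 sd wave span exceeds the RR interval are rejected as
ambiguous morphology.

What the generator deliberately does **not** emulate: realistic P
waves (see the detector limitations above — default P amplitude is
0.01 mV), QRS axis and conduction physiology, arrhythmia, muscle-noise
spectra, electrode artefacts. Passing tests on this generator therefore
demonstrate that the *algorithms* implement their stated rules and
recover planted structure — not that the pipeline performs at any
particular level on clinical recordings.

`synth_cohort()` draws a labelled two-class population: per-subject
per-lead log-normal gain scatter (sd 0.12), heart rates uniform in
60–95 bpm, 90% male, and an LVH effect implemented as a subject-level
multiplier (mean 1.9, sd 0.25, truncated at 1.1) on the S amplitudes of
V1–V3 and the R amplitudes of aVL/V5/V6 — the leads the criteria read.
Each subject receives an LVMI drawn from class- and sex-appropriate
ranges so the threshold labelling rule reproduces the class exactly.
`synth_feature_table()` skips the signal level entirely: standard-normal
features with a configurable mean shift on a chosen subset, used for
classifier parameter-recovery and permutation-null experiments
(effect 3 sd on 6 features at n = 400/class is the recovery condition;
the BPN must reach ≥ 0.95 held-out accuracy there and chance on
permuted labels).

## Numerical and design choices

* Ties in argmin/argmax: earliest index, everywhere.
* Window sample counts: `round(duration × fs)`, half-up.
* Even-count medians: mean of the two middle values.
* Population-sd z-scores; sd clamp at 1e-12.
* Depth ties: smallest depth. Cluster-label ties at 0.5: positive.
* Undefined metric ratios: `NA`.
* The WFDB reader/writer covers exactly the subset needed (single
  format-16 signal file, case-insensitive canonical lead names;
  unmapped names are an error, not a guess), since no R WFDB reader is
  available on CRAN/Bioconductor.
* CSV sample export uses `%.17g`, keeping write→read round trips
  bit-exact for doubles.

## Problem sizes used in the test suite

Oracle equivalence runs 1,000 random signals; the T-correction suite
100 records; the F-statistic oracle 1,000 instances; BPN recovery
n = 400/class; the end-to-end pipeline a 60-subject cohort at full
11 s × 500 Hz resolution, run twice to verify bit-reproducibility.
These sizes keep the whole suite within a couple of minutes on one CPU
while leaving each property's sampling dense enough to be meaningful.

## Known limitations

* The detector inherits the fragility of its amplitude floor: P waves
  or noise above 0.025 mV derail the greedy scan (documented above).
  Heart rates outside 60–100 bpm are not guaranteed — except that the
  T-correction specifically targets the RR < 0.6 s regime.
* Beat-level training numbers depend strongly on grouped vs ungrouped
  splitting; both are available, grouped is default.
* The k-means classifier ignores labels during fitting by
  construction; it is included as a protocol baseline, not a
  recommendation.
* Criteria thresholds are population-calibrated values from the
  literature; on synthetic cohorts their sensitivity/specificity
  reflect the generator's effect sizes, not clinical performance.
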
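---
title: "Methods: microstate segmentation, omega complexity, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microstate segmentation, omega complexity, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the methods it implements:
the models, the tunable parameters and why their defaults are what they are,
the numerical edge cases, and what the synthetic-data validation does and
does not establish about real recordings.

## Preprocessing

The chain (`preprocess_recording()`) reduces a continuous multichannel
recording to average-referenced 2,000-ms epochs on the 19-channel 10–20
montage: montage reduction, resampling to 125 Hz, 1–60 Hz band-pass, 50 Hz
notch, segmentation, selection of the first 20 epochs, average reference.

* **Filters.** All filtering is 4th-order Butterworth applied
  forward–backward (`signal::filtfilt`), so the net filter has zero phase:
  microstate metrics are segment-timing statistics, and any group delay
  would bias them. The band-pass is built as a high-pass/low-pass cascade
  rather than a single band design because the 60 Hz edge sits close to the
  62.5 Hz Nyquist frequency at 125 Hz, where a combined design is
  numerically fragile. Channel means are removed before the high-pass: the
  forward–backward filter's edge transients handle large DC offsets poorly.
* **Notch.** 50 Hz by default (configurable), with a ±2 Hz stop band: narrow
  enough to leave broadband power essentially untouched, wide enough for a
  deep null at the mains frequency after the forward–backward pass.
* **Epoching.** Non-overlapping epochs; a trailing remainder shorter than
  one epoch is discarded — the simplest deterministic rule. Epoch selection
  takes the first *n* in recording order.
* **Out of scope.** Artifact handling (visual rejection, ICA, channel
  interpolation) is an upstream responsibility for real data; the synthetic
  generator produces artifact-free signals.

## Microstate segmentation

GFP is computed as the *population* spatial standard deviation (dividing by
the channel count), the field's usual convention. GFP peaks are strict
interior local maxima; on a plateau of equal values the first sample counts,
and no minimum peak distance is imposed.

**T-AAHC.** Each GFP-peak map starts as its own cluster. At every step the
cluster contributing least global explained variance — the GFP²-weighted sum
of squared polarity-invariant correlations of members to their prototype —
is *atomized*: dissolved, with each member reassigned to the surviving
cluster of maximal absolute spatial correlation. A cluster's prototype is
the first principal component of its member maps (computed from the member
scatter matrix, hence inherently polarity-invariant), sign-aligned to its
heaviest member and normalized to unit GFP. Clustering stops at `k = 4`
clusters, the conventional choice that keeps classes comparable across the
literature. The loop is implemented in C++ (RcppArmadillo); clustering the
pooled peaks of a 10-subject, 40-s-per-subject group (~8,000 maps) takes a
few seconds.

**Labeling.** Clustered prototypes are labeled A–D against canonical
template maps by the permutation maximizing total absolute correlation,
exhaustively over all 24 assignments. The templates are built analytically
from the montage geometry along the four canonical axes (A right-frontal ↔
left-occipital, B left-frontal ↔ right-occipital, C prefrontal ↔ occipital,
D frontocentral focus vs. occiput); they are package fixtures, replaceable
by any user-supplied `prototype_set`.

**Back-fitting.** Every sample is assigned the prototype with maximal
absolute spatial correlation, independently per sample. Zero-variance
samples (possible in synthetic data when the carrier crosses zero) inherit
the nearest labeled neighbor within the epoch and are counted in an
attribute. A `min_duration_ms` post-pass is available (default off):
segments shorter than the floor are merged into the better-fitting
neighbor, shortest first.

**Parameters.** Segments are maximal within-epoch runs of one label.
Duration is the mean length of *complete* runs — runs touching an epoch
boundary were truncated by segmentation, so counting them would bias
duration downward; occurrence counts complete runs per second of analyzed
time; coverage is the time fraction over *all* samples, so it remains a true
occupancy and sums to 100%. A class with no complete run reports `NA`
duration (undefined, not zero). Transition probabilities are conditional
(row-normalized) counts of consecutive distinct labels within epochs only;
rows without outgoing transitions are `NA`, and the diagonal is zero by
construction. One consequence worth knowing: the identity
occurrence × duration ≈ coverage holds only when boundary-truncated runs
hold a negligible time share — with 2-s epochs and ~80 ms dwell times the
truncated share is ~8%, so the identity is only approximate at that epoch
length.

**Duration vs. coverage.** Where the terminology in parts of this
literature conflates "duration" with "time coverage", this package uses the
standard meanings: duration = mean uninterrupted segment length, coverage =
occupancy fraction.

**Group analysis.** `run_group_microstate()` pools GFP-peak maps across the
subjects of one group, clusters once, labels, and back-fits the group
prototypes to every subject — prototypes are estimated per group, as is
conventional; a shared-template mode (`shared_templates`) is available when
strict cross-group comparability of templates is preferred.

## Omega spatial complexity

Per epoch, the channel covariance (time mean removed) is built for the
global 19-channel set and the 7-channel anterior and posterior subsets.
Eigenvalues are clipped at zero when within floating-point noise
(−1e−10 × max) and rejected as errors beyond that; after unit-sum
normalization, omega is the exponential of the Shannon entropy with the
0·log 0 := 0 convention. The natural logarithm makes the upper bound exact:
a uniform spectrum over *k* electrodes gives Ω = k, and a rank-1 spectrum
gives Ω = 1.

Choices where the procedure is under-specified:

* **Covariance, not correlation**, matching the stated construction;
  a correlation option exists because heterogeneous channel variances
  otherwise contribute to Ω.
* **Per-epoch Ω averaged across epochs** (default), robust to
  nonstationarity and consistent with the epoched pipeline; a concatenated
  mode pools all epochs into one covariance.
* **Broadband input** (the 1–60 Hz preprocessed epochs), not the 2–20 Hz
  microstate band — the complexity analysis is a separate branch of the
  pipeline.
* The summation index is treated as the *component* index (the standard
  eigenvalue-entropy definition), not an electrode index.

## The synthetic cohort generator

The generator exists so that every downstream stage has a recoverable
target. It emulates: 19-channel average-referenced EEG at 125 Hz in 2,000-ms
epochs; four quasi-stable dipolar topographies alternating on the canonical
60–120 ms timescale; an alpha (10 Hz) carrier, since microstate dynamics are
dominated by alpha-band rhythms; and controllable group differences in dwell
times, syntax, and spatial covariance rank.

* **Dwell times** are gamma with shape 2 (mean = the class's
  `mean_duration_ms`), discretized and floored at 2 samples. A geometric
  law would produce an implausible excess of 1-sample states; shape 2 gives
  a realistic unimodal dwell distribution. The epoch boundary truncates the
  final run — sequences never cross epochs.
* **Carrier polarity** flips randomly per run (phase 0 or π), so the
  polarity invariance of clustering and back-fitting is genuinely exercised
  rather than vacuously true.
* **Noise** is Gaussian with a covariance built from a random orthonormal
  basis and geometrically decaying eigenvalues down to the stated rank —
  rank is the direct control for the omega target. The patient-like spec
  additionally injects independent components confined to the anterior
  electrodes, raising anterior Ω specifically. Signal-to-noise is the ratio
  of mean signal power to mean noise power across channels and samples
  (default 10).
* **Group archetypes.** The control-like spec uses dwell means of 70–90 ms,
  near-uniform syntax with mildly elevated A→B/A→C mass, and rank-6 noise.
  The patient-like spec lengthens dwell times (means 80–110 ms, hence fewer
  onsets), shifts transition mass toward B↔D and away from A→B/A→C, and
  adds the anterior noise components. No quantitative effect sizes on the
  generative scale are available from group-level F statistics alone, so
  the default gaps are chosen for detectability at n = 20/20 — they are
  calibration targets, not estimates of clinical effect magnitude.
* **Subjects** get log-normal jitter on dwell means (sdlog 0.06) and on
  transition mass (sdlog 0.10, rows renormalized), a small smooth
  perturbation of the prototype maps, and ages from group-specific normal
  models (means 68.2/69.3, sd 5.4/6.9 years) truncated to 60–90. Subject
  seeds derive from the master seed by a counter, so enlarging a cohort
  never reshuffles existing subjects.

**What passing recovery tests does and does not show.** The generator's
signals are piecewise prototype-times-sinusoid with additive Gaussian noise:
no 1/f background, no artifacts, no volume-conduction forward model, no
within-subject nonstationarity. Recovery of ground truth under these
conditions validates the *implementation* — the clustering, labeling,
back-fitting, counting and eigen-decomposition arithmetic — not the
sensitivity of the method on clinical EEG.

**Analysis configuration for synthetic recovery.** Two configuration
choices matter when validating against ground truth. First, the 2–20 Hz
microstate band-pass is skipped for generator output: the synthetic signal
is already carried at 10 Hz, and filtering only smears the instantaneous
prototype switches across samples (real data, with drift and broadband
artifacts, still wants the filter). Second, back-fitting uses
`min_duration_ms = 16` — exactly the 2-sample dwell floor the generator
itself imposes. At the default SNR the carrier's zero crossings leave
isolated 1-sample samples ambiguous; a 16-ms floor removes only segments
the generative model cannot produce, without touching any legitimate run.
With both settings, back-fit estimates recover realized per-subject
duration, occurrence and coverage to within 10% relative error and
transition probabilities to within ±0.05 (tested on a 20-subject cohort at
40 s per subject).

## Statistics

`ancova_univariate()` fits `y ~ age + group` by least squares and tests the
group effect marginally (type III — full vs. group-dropped model), with
partial η² = SS(group)/(SS(group)+SS(error)). `rm_ancova()` implements the
univariate mixed design: the between stratum is an ANCOVA on subject means
(group tested against subject-to-subject error, age centered before entry);
the within stratum tests class and class × group against the
class × subject error. The Greenhouse–Geisser ε of the within-subject
covariance is always reported and optionally applied; the covariate is not
crossed with the within factor (some software does cross it by default —
that choice mainly affects the within-stratum error term, and keeping the
covariate between-subject keeps the class effects interpretable as raw
within-subject contrasts). Bonferroni families are declared explicitly: the
4 classes within each parameter, the 12 ordered transition pairs, the 3
omega regions. Demographic comparisons use the pooled-variance t and the
Pearson chi-square without continuity correction.

Calibration and power are validated by simulation in the test suite:
type-I error of the ANCOVA on null cohorts (identical generative specs,
200 replicates at n = 20/20) must lie in 0.05 ± 0.02, and the default group
contrast must be detected with power ≥ 0.8 (40 replicates) in duration,
occurrence, B↔D transitions and anterior omega, each in the expected
direction. The calibration replicates generate label sequences only
(`synthesize = FALSE`), since dwell statistics do not depend on the EEG
synthesis stage; the power replicates synthesize EEG so the anterior-omega
effect passes through the full spatial pipeline.

## Problem sizes and runtime

The shipped tests use desk-scale sizes chosen to exercise every code path:
cohorts of 20–40 subjects at 20 × 2-s epochs, clustering inputs up to
~16,000 pooled maps, 200 calibration and 40 power replicates. The full
suite runs in about four minutes on one CPU.

## Known limitations

* The EDF reader/writer covers the plain 16-bit EDF subset (uniform
  sampling rate, no annotations); EDF+ extensions are not parsed.
* No artifact simulation or forward head-modeling; synthetic validation is
  an implementation check, not a clinical-sensitivity study.
* `signal::filtfilt` handles edges by simple reversal without initial-state
  optimization; filters are applied after demeaning to compensate, and a
  symmetric pulse round-trips with <0.5% asymmetry in the tests.
* Repeated-measures p-values assume sphericity unless the
  Greenhouse–Geisser correction is enabled.
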